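#' Read a bedGraph signal track
#'
#' Parses a four-column bedGraph file (chrom, start, end, value) into a
#' tibble of signal intervals. `track`, `browser` and `#` comment lines and
#' blank lines are skipped. Coordinates are kept 0-based half-open as in
#' the bedGraph standard. Malformed lines (not 4 fields, non-numeric value
#' or coordinates, start >= end) raise an error naming the line number.
#'
#' @param path path to a bedGraph text file.
#' @return Tibble with columns `chrom` (character), `start`, `end`
#'   (0-based half-open integers) and `value` (double).
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path)
  skip <- grepl("^\\s*$|^track\\b|^browser\\b|^#", lines)
  keep <- which(!skip)
  if (length(keep) == 0L)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = double()))
  fields <- strsplit(lines[keep], "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop_bad("bedGraph parse error at line %d: expected 4 fields, got %d",
             keep[which(nf != 4L)[1]], nf[nf != 4L][1])
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop_bad("bedGraph parse error at line %d: non-numeric field", keep[bad[1]])
  rev_coord <- which(start >= end)
  if (length(rev_coord))
    stop_bad("bedGraph parse error at line %d: start >= end",
             keep[rev_coord[1]])
  tibble(chrom = m[, 1], start = as.integer(start), end = as.integer(end),
         value = value)
}

#' Write signal intervals as bedGraph
#'
#' @param intervals tibble with `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @param track_line optional `track ...` header line.
#' @export
write_bedgraph <- function(intervals, path, track_line = NULL) {
  body <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                  as.integer(intervals$start), as.integer(intervals$end),
                  format(intervals$value, trim = TRUE, digits = 6,
                         scientific = FALSE))
  readr::write_lines(c(track_line, body), path)
  invisible(path)
}

#' Read gene regions from a BED file
#'
#' Reads the first four columns of a BED file (chrom, start, end, name);
#' coordinates stay 0-based half-open. Intervals with a missing name get
#' `region_<i>`.
#'
#' @param path path to a BED text file.
#' @return Tibble with `chrom`, `start`, `end`, `gene`.
#' @export
read_bed_regions <- function(path) {
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*$|^track\\b|^browser\\b|^#", lines))
  if (length(keep) == 0L)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene = character()))
  fields <- strsplit(lines[keep], "\\s+")
  if (any(lengths(fields) < 3L))
    stop_bad("BED parse error at line %d: fewer than 3 fields",
             keep[which(lengths(fields) < 3L)[1]])
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- as.integer(vapply(fields, `[`, character(1), 2))
  end <- as.integer(vapply(fields, `[`, character(1), 3))
  gene <- vapply(seq_along(fields), function(i)
    if (lengths(fields)[i] >= 4L) fields[[i]][4] else
      sprintf("region_%d", i), character(1))
  if (any(is.na(start) | is.na(end)) || any(start >= end))
    stop_bad("BED parse error: bad coordinates")
  tibble(chrom = chrom, start = start, end = end, gene = gene)
}

# GRanges from a 0-based half-open interval tibble (shift to 1-based closed)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Percentile threshold of a signal distribution
#'
#' q-th percentile by linear interpolation between closest order
#' statistics, index `h = (n - 1) * q / 100` (the type-7 convention).
#'
#' @param values numeric vector (>= 1 value).
#' @param q percentile in `[0, 100]` (default 95, the Input-distribution
#'   enrichment cutoff).
#' @return the threshold value.
#' @examples
#' percentile_threshold(1:100, 95)  # 95.05
#' @export
percentile_threshold <- function(values, q = 95) {
  if (length(values) < 1L) stop_bad("percentile of an empty set is undefined")
  stopifnot(q >= 0, q <= 100)
  unname(quantile(values, q / 100, type = 7, names = FALSE))
}

#' Filter ChIP intervals enriched over the Input distribution
#'
#' Implements the percentile enrichment rule: restrict the Input signal to
#' intervals overlapping any analyzed gene region, take its q-th percentile
#' as the threshold, and keep exactly those ChIP intervals that (i) overlap
#' a gene region and (ii) have signal value strictly greater than the
#' threshold. Each kept interval is annotated with the overlapping gene
#' label(s), comma-joined when a peak spans several regions.
#'
#' @param chip tibble of ChIP signal intervals (`chrom`, `start`, `end`,
#'   `value`; 0-based half-open), e.g. from [read_bedgraph()].
#' @param input_signal tibble of Input control intervals, same columns.
#' @param regions tibble of gene regions (`chrom`, `start`, `end`, `gene`),
#'   e.g. from [read_bed_regions()].
#' @param q percentile of the Input distribution (default 95).
#' @param input_scope `"regions"` draws the Input distribution only from
#'   intervals overlapping the analyzed regions (default); `"genome"` uses
#'   every Input interval.
#' @param weight_by_base when `TRUE`, the Input percentile weights each
#'   interval's value by its base-pair span instead of one value per
#'   interval.
#' @param min_value optional pre-filter: Input and ChIP intervals with
#'   value below this are discarded before anything else.
#' @return Tibble of enriched ChIP intervals (`chrom`, `start`, `end`,
#'   `value`, `genes`), a subset of `chip`, with the threshold used and
#'   interval counts attached as attributes `threshold`, `n_chip_in_regions`
#'   and `n_input_used`.
#' @export
filter_enriched_intervals <- function(chip, input_signal, regions, q = 95,
                                      input_scope = c("regions", "genome"),
                                      weight_by_base = FALSE,
                                      min_value = NULL) {
  input_scope <- match.arg(input_scope)
  chip <- as_tibble(chip); input_signal <- as_tibble(input_signal)
  regions <- as_tibble(regions)
  if (!is.null(min_value)) {
    chip <- chip[chip$value >= min_value, ]
    input_signal <- input_signal[input_signal$value >= min_value, ]
  }
  gr_reg <- as_granges0(regions)
  if (input_scope == "regions") {
    if (nrow(input_signal))
      input_used <- input_signal[
        suppressWarnings(
          IRanges::overlapsAny(as_granges0(input_signal), gr_reg)), ]
    else input_used <- input_signal
    if (nrow(input_used) == 0L)
      stop_bad("no Input interval overlaps any analyzed region")
  } else {
    input_used <- input_signal
    if (nrow(input_used) == 0L) stop_bad("empty Input signal")
  }
  vals <- if (weight_by_base)
    rep(input_used$value, times = input_used$end - input_used$start)
  else input_used$value
  thr <- percentile_threshold(vals, q)

  if (nrow(chip) == 0L) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  value = double(), genes = character())
  } else {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(as_granges0(chip), gr_reg))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    genes_by_chip <- tapply(regions$gene[sh], qh,
                            function(g) paste(unique(g), collapse = ","))
    in_reg <- as.integer(names(genes_by_chip))
    keep <- in_reg[chip$value[in_reg] > thr]
    out <- chip[keep, ]
    out$genes <- unname(genes_by_chip[as.character(keep)])
    out <- out[order(out$chrom, out$start), ]
  }
  n_chip_in_regions <- if (nrow(chip))
    sum(suppressWarnings(
      IRanges::overlapsAny(as_granges0(chip), gr_reg))) else 0L
  attr(out, "threshold") <- thr
  attr(out, "n_chip_in_regions") <- n_chip_in_regions
  attr(out, "n_input_used") <- nrow(input_used)
  out
}
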