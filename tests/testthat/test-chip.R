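test_that("bedGraph parsing keeps 0-based half-open coordinates and skips headers", {
  path <- write_lines_tmp(c(
    "track type=bedGraph name=\"input\"",
    "# a comment",
    "chr1\t100\t200\t5.29",
    "chr2 300 450 1.5"), ".bedGraph")
  iv <- read_bedgraph(path)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(100L, 300L))
  expect_equal(iv$end, c(200L, 450L))
  expect_equal(iv$value, c(5.29, 1.5))
})

test_that("malformed bedGraph lines raise errors naming the line", {
  p3 <- write_lines_tmp(c("chr1\t1\t10\t2", "chr1\t20\t30"), ".bedGraph")
  expect_error(read_bedgraph(p3), "line 2")
  pnum <- write_lines_tmp(c("track x", "chr1\t1\tten\t2"), ".bedGraph")
  expect_error(read_bedgraph(pnum), "line 2")
  prev <- write_lines_tmp(c("chr1\t50\t40\t2"), ".bedGraph")
  expect_error(read_bedgraph(prev), "line 1.*start >= end")
})

test_that("bedGraph write/read round trip is lossless", {
  iv <- tibble::tibble(chrom = c("chr1", "chr1", "chrX"),
                       start = c(0L, 500L, 10L), end = c(100L, 900L, 20L),
                       value = c(0.125, 7.5, 42))
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(iv, path, track_line = "track type=bedGraph")
  expect_equal(as.data.frame(read_bedgraph(path)), as.data.frame(iv))
})

test_that("parsed coordinates agree with rtracklayer on the same file", {
  path <- write_lines_tmp(c("chr1\t100\t200\t5.5", "chr1\t250\t300\t2"),
                          ".bedGraph")
  iv <- read_bedgraph(path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  # rtracklayer is 1-based closed; ours is 0-based half-open
  expect_equal(iv$start + 1L, GenomicRanges::start(gr))
  expect_equal(iv$end, GenomicRanges::end(gr))
  expect_equal(iv$value, gr$score)
})

test_that("percentile threshold follows the linear-interpolation convention", {
  expect_equal(percentile_threshold(1:100, 95), 95.05)
  expect_equal(percentile_threshold(rep(3.7, 10), 20), 3.7)
  expect_equal(percentile_threshold(rep(3.7, 10), 95), 3.7)
  expect_equal(percentile_threshold(5, 50), 5)
  expect_error(percentile_threshold(numeric(0), 95), "empty")
  set.seed(4)
  v <- rexp(201)
  expect_equal(percentile_threshold(sample(v), 95),
               percentile_threshold(v, 95))  # permutation invariance
})

test_that("enrichment keeps only in-region intervals strictly above the threshold", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                            gene = "Mapt")
  # Input values all 5.29 -> threshold 5.29 at any percentile
  input <- tibble::tibble(chrom = "chr1", start = seq(0L, 900L, 100L),
                          end = seq(100L, 1000L, 100L), value = 5.29)
  chip <- tibble::tibble(chrom = "chr1", start = c(10L, 200L, 400L),
                         end = c(60L, 260L, 450L), value = c(2, 6, 10))
  out <- filter_enriched_intervals(chip, input, regions, q = 95)
  expect_equal(attr(out, "threshold"), 5.29)
  expect_equal(sort(out$value), c(6, 10))  # 5.29 rule is strictly greater
  expect_true(all(out$genes == "Mapt"))
})

test_that("overlap is half-open: touching intervals do not overlap", {
  regions <- tibble::tibble(chrom = "chr1", start = 150L, end = 300L,
                            gene = "geneA")
  input <- tibble::tibble(chrom = "chr1", start = 150L, end = 300L, value = 1)
  chip <- tibble::tibble(chrom = "chr1",
                         start = c(100L, 50L), end = c(200L, 150L),
                         value = c(9, 9))
  out <- filter_enriched_intervals(chip, input, regions, q = 50)
  expect_equal(nrow(out), 1L)          # [100,200) overlaps, [50,150) only touches
  expect_equal(out$start, 100L)
  expect_equal(out$genes, "geneA")
})

test_that("empty ChIP input yields an empty result but still reports the threshold", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                            gene = "g")
  input <- tibble::tibble(chrom = "chr1", start = 10L, end = 90L, value = 2)
  empty_chip <- tibble::tibble(chrom = character(), start = integer(),
                               end = integer(), value = double())
  out <- filter_enriched_intervals(empty_chip, input, regions, q = 95)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "threshold"), 2)
  far_input <- tibble::tibble(chrom = "chr9", start = 10L, end = 90L,
                              value = 2)
  expect_error(filter_enriched_intervals(empty_chip, far_input, regions),
               "no Input interval overlaps")
})

test_that("raising the percentile never enlarges the enriched set", {
  set.seed(14)
  regions <- tibble::tibble(chrom = c("chr1", "chr2"),
                            start = c(500L, 1000L), end = c(2500L, 3000L),
                            gene = c("g1", "g2"))
  chip <- random_signal_tibble(300)
  input <- random_signal_tibble(300)
  prev_n <- Inf
  for (q in c(10, 50, 80, 95, 99)) {
    out <- filter_enriched_intervals(chip, input, regions, q = q)
    expect_lte(nrow(out), prev_n)
    prev_n <- nrow(out)
  }
})

test_that("enrichment equals a brute-force interval scan on random bedGraphs", {
  set.seed(77)
  for (rep in 1:25) {
    regions <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 3, replace = TRUE),
      start = sample.int(3000, 3), gene = paste0("g", 1:3))
    regions$end <- regions$start + sample.int(800, 3)
    chip <- random_signal_tibble(sample(20:120, 1))
    input <- random_signal_tibble(sample(20:120, 1))
    q <- sample(c(50, 80, 95), 1)
    orc <- tryCatch(brute_force_enrichment(chip, input, regions, q),
                    error = function(e) NULL)
    if (is.null(orc)) next  # no input overlap drawn; package errors too
    out <- filter_enriched_intervals(chip, input, regions, q = q)
    expect_equal(attr(out, "threshold"), orc$threshold, tolerance = 1e-12)
    a <- dplyr::arrange(out[, c("chrom", "start", "end", "value")],
                        chrom, start, end)
    b <- dplyr::arrange(orc$kept, chrom, start, end)
    expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
  }
})

test_that("base-weighted percentile weights interval values by span", {
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L,
                            gene = "g")
  input <- tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                          end = c(100L, 110L), value = c(1, 11))
  chip <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L, value = 100)
  out_plain <- filter_enriched_intervals(chip, input, regions, q = 50)
  out_wt <- filter_enriched_intervals(chip, input, regions, q = 50,
                                      weight_by_base = TRUE)
  expect_equal(attr(out_plain, "threshold"), 6)   # median of {1, 11}
  expect_equal(attr(out_wt, "threshold"),
               percentile_threshold(rep(c(1, 11), c(100, 10)), 50))
})
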