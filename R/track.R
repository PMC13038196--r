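#' @title Frame-to-frame LAP track linking
#' @description The linking stage of the comet pipeline: a rectangular
#'   linear-assignment solver with a per-item non-link cost (the
#'   distance-cutoff-as-cost convention of simple LAP particle trackers),
#'   frame-to-frame linking on squared Euclidean distance, and an optional
#'   second gap-closing pass joining track ends to later track starts.
#' @name comet_tracking
NULL

# Jonker-Volgenant shortest augmenting path LAP on a square finite matrix.
# Returns col assignment per row. O(n^3); rows are augmented in index order
# and ties resolved by the first minimal column, so the result is
# deterministic.
lap_jv <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)           # p[j] = row matched to column j (0 = none)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[seq_len(n)]
      upd <- !used[seq_len(n)] & cur < minv
      minv[upd] <- cur[upd]
      way[upd] <- j0
      free <- which(!used[seq_len(n)])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      nf <- !used[seq_len(n)]
      minv[nf] <- minv[nf] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign <- integer(n)
  assign[p[seq_len(n)]] <- seq_len(n)
  assign
}

#' Solve a linking assignment with a non-link cost
#'
#' Minimum-total-cost matching between the rows and columns of a cost
#' matrix where any row or column may instead stay unmatched at a price of
#' `nonlink_cost`. The non-link cost doubles as a cutoff: entries greater
#' than `nonlink_cost` (and `Inf` entries) are forbidden and never linked,
#' the convention that turns a maximum linking distance into an assignment
#' cost. Implemented as a Jonker-Volgenant solve on the standard augmented
#' matrix (real costs top-left, `nonlink_cost` on the dummy diagonals,
#' zero dummy-dummy block). Rows are processed in index order and
#' equal-cost alternatives resolved by the smallest column index, making
#' the output deterministic.
#'
#' @param cost_matrix numeric matrix (possibly 0-row/0-col) of non-negative
#'   finite costs, `Inf` allowed for forbidden pairs.
#' @param nonlink_cost cost (> 0) of leaving one row or one column
#'   unmatched.
#' @return List with `matches` (tibble `row`, `col`, `cost`),
#'   `unmatched_rows`, `unmatched_cols`, and `total_cost` (sum of matched
#'   costs plus `nonlink_cost` per unmatched row/column).
#' @examples
#' solve_assignment(matrix(c(1, 8, 8, 2), 2), nonlink_cost = 5)
#' @export
solve_assignment <- function(cost_matrix, nonlink_cost) {
  stopifnot(is.matrix(cost_matrix) || length(cost_matrix) == 0L,
            nonlink_cost > 0)
  if (!is.matrix(cost_matrix)) cost_matrix <- matrix(numeric(0), 0, 0)
  nr <- nrow(cost_matrix); nc <- ncol(cost_matrix)
  if (any(cost_matrix[is.finite(cost_matrix)] < 0))
    stop_bad("costs must be non-negative")
  if (nr == 0L && nc == 0L)
    return(list(matches = tibble(row = integer(), col = integer(),
                                 cost = numeric()),
                unmatched_rows = integer(), unmatched_cols = integer(),
                total_cost = 0))
  n <- nr + nc
  finite_max <- suppressWarnings(max(cost_matrix[is.finite(cost_matrix)], 0))
  big <- (finite_max + nonlink_cost + 1) * (n + 1)
  aug <- matrix(0, n, n)
  tl <- cost_matrix
  tl[!is.finite(tl) | tl > nonlink_cost] <- big
  aug[seq_len(nr), seq_len(nc)] <- tl
  aug[seq_len(nr), nc + seq_len(nr)] <- big
  aug[nr + seq_len(nc), seq_len(nc)] <- big
  for (i in seq_len(nr)) aug[i, nc + i] <- nonlink_cost
  for (j in seq_len(nc)) aug[nr + j, j] <- nonlink_cost
  assign <- lap_jv(aug)
  rows <- seq_len(nr)
  linked <- rows[assign[rows] <= nc]
  lcost <- cost_matrix[cbind(linked, assign[linked])]
  linked <- linked[is.finite(lcost) & lcost <= nonlink_cost]
  matches <- tibble(row = linked, col = assign[linked],
                    cost = cost_matrix[cbind(linked, assign[linked])])
  unmatched_rows <- setdiff(rows, matches$row)
  unmatched_cols <- setdiff(seq_len(nc), matches$col)
  list(matches = matches,
       unmatched_rows = unmatched_rows,
       unmatched_cols = unmatched_cols,
       total_cost = sum(matches$cost) +
         nonlink_cost * (length(unmatched_rows) + length(unmatched_cols)))
}

#' Linking parameters for the simple LAP tracker
#'
#' @param max_link_dist_px maximum frame-to-frame linking distance (px).
#' @param gap_frames maximum number of skipped frames a gap-closing link may
#'   bridge; 0 disables gap closing (default).
#' @param max_gap_dist_px maximum distance for a gap-closing link (px);
#'   defaults to `max_link_dist_px`.
#' @param min_track_len minimum number of detections a track must keep
#'   (>= 2); default 4 so that angle fluctuation (needing at least two
#'   direction changes, i.e. three steps) is computable.
#' @param alt_cost_factor multiplier on `max_link_dist_px` when forming the
#'   non-link cost `(alt_cost_factor * max_link_dist_px)^2`; default 1.
#' @return A `linking_params` list.
#' @export
linking_params <- function(max_link_dist_px, gap_frames = 0L,
                           max_gap_dist_px = max_link_dist_px,
                           min_track_len = 4L, alt_cost_factor = 1) {
  stopifnot(max_link_dist_px > 0, gap_frames >= 0, max_gap_dist_px > 0,
            min_track_len >= 2, alt_cost_factor > 0)
  structure(list(max_link_dist_px = max_link_dist_px,
                 gap_frames = as.integer(gap_frames),
                 max_gap_dist_px = max_gap_dist_px,
                 min_track_len = as.integer(min_track_len),
                 alt_cost_factor = alt_cost_factor),
            class = "linking_params")
}

#' Link per-frame detections into comet tracks
#'
#' Frame-to-frame linear assignment with cost equal to squared Euclidean
#' distance; links beyond `max_link_dist_px` are forbidden and the non-link
#' cost is `(alt_cost_factor * max_link_dist_px)^2`. If `gap_frames > 0`, a
#' second assignment pass joins track ends to track starts separated by at
#' most `gap_frames` skipped frames and `max_gap_dist_px` pixels. Tracks
#' shorter than `min_track_len` detections are dropped and counted.
#'
#' Detections are canonically ordered within each frame before linking, so
#' the result does not depend on input row order.
#'
#' @param detections tibble with columns `frame`, `x_px`, `y_px` (extra
#'   columns are carried through).
#' @param params a [linking_params()].
#' @return Tibble with columns `track_id`, `frame`, `x_px`, `y_px`,
#'   `gaps_closed` (gaps closed in that detection's track) plus carried
#'   columns; attribute `n_dropped` holds the number of tracks removed by
#'   the length filter.
#' @export
link_tracks <- function(detections, params) {
  stopifnot(inherits(params, "linking_params"))
  det <- as_tibble(detections)
  req <- c("frame", "x_px", "y_px")
  if (!all(req %in% names(det)))
    stop_bad("detections need columns frame, x_px, y_px")
  if (is.unsorted(det$frame)) det <- det[order(det$frame), ]
  det <- det[order(det$frame, det$y_px, det$x_px), ]
  n <- nrow(det)
  if (n == 0L) {
    out <- tibble(track_id = integer(), frame = integer(),
                  x_px = numeric(), y_px = numeric(),
                  gaps_closed = integer())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  nonlink <- (params$alt_cost_factor * params$max_link_dist_px)^2
  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(n), det$frame)

  succ <- integer(n)  # successor detection index within a track (0 = none)
  has_pred <- logical(n)
  for (fi in seq_along(frames)[-1]) {
    if (frames[fi] - frames[fi - 1] != 1L) next
    a <- by_frame[[as.character(frames[fi - 1])]]
    b <- by_frame[[as.character(frames[fi])]]
    cost <- outer(det$x_px[a], det$x_px[b], "-")^2 +
      outer(det$y_px[a], det$y_px[b], "-")^2
    cost[cost > params$max_link_dist_px^2] <- Inf
    sol <- solve_assignment(cost, nonlink)
    succ[a[sol$matches$row]] <- b[sol$matches$col]
    has_pred[b[sol$matches$col]] <- TRUE
  }

  # walk chains from detections with no predecessor
  track_of <- integer(n)
  starts <- which(!has_pred)
  tid <- 0L
  for (s in starts) {
    tid <- tid + 1L
    k <- s
    while (k != 0L) { track_of[k] <- tid; k <- succ[k] }
  }
  n_tracks <- tid
  gaps_closed <- integer(n_tracks)

  if (params$gap_frames > 0L && n_tracks > 1L) {
    first_idx <- vapply(seq_len(n_tracks), function(t)
      which(track_of == t)[which.min(det$frame[track_of == t])], integer(1))
    last_idx <- vapply(seq_len(n_tracks), function(t)
      which(track_of == t)[which.max(det$frame[track_of == t])], integer(1))
    gap <- outer(det$frame[first_idx], det$frame[last_idx], "-") - 1L
    d2 <- outer(det$x_px[first_idx], det$x_px[last_idx], "-")^2 +
      outer(det$y_px[first_idx], det$y_px[last_idx], "-")^2
    feasible <- gap >= 1L & gap <= params$gap_frames &
      d2 <= params$max_gap_dist_px^2
    cost <- t(ifelse(feasible, d2, Inf))   # rows = ends, cols = starts
    diag_self <- cbind(seq_len(n_tracks), seq_len(n_tracks))
    cost[diag_self] <- Inf
    if (any(is.finite(cost))) {
      sol <- solve_assignment(cost, params$max_gap_dist_px^2)
      # merge: end of track r joins start of track c
      parent <- seq_len(n_tracks)
      find_root <- function(t) { while (parent[t] != t) t <- parent[t]; t }
      n_joined <- integer(n_tracks)
      if (nrow(sol$matches) > 0) for (m in seq_len(nrow(sol$matches))) {
        r <- sol$matches$row[m]; cl <- sol$matches$col[m]
        succ[last_idx[r]] <- first_idx[cl]
        rr <- find_root(r)
        parent[cl] <- rr
        n_joined[rr] <- n_joined[rr] + n_joined[cl] + 1L
      }
      roots <- vapply(seq_len(n_tracks), find_root, integer(1))
      track_of <- roots[track_of]
      gaps_closed <- integer(n_tracks)
      gaps_closed[seq_along(n_joined)] <- n_joined
    }
  }

  det$track_id <- track_of
  det$gaps_closed <- gaps_closed[track_of]
  counts <- table(det$track_id)
  keep_ids <- as.integer(names(counts)[counts >= params$min_track_len])
  n_dropped <- length(counts) - length(keep_ids)
  det <- det[det$track_id %in% keep_ids, ]
  det <- det[order(det$track_id, det$frame), ]
  # dense ids ordered by first appearance (birth frame, canonical order)
  first_frame <- tapply(det$frame, det$track_id, min)
  ord <- order(first_frame, as.integer(names(first_frame)))
  remap <- stats::setNames(seq_along(ord), names(first_frame)[ord])
  det$track_id <- unname(remap[as.character(det$track_id)])
  det <- det[order(det$track_id, det$frame), ]
  out <- dplyr::relocate(det, "track_id", "frame", "x_px", "y_px",
                         "gaps_closed")
  attr(out, "n_dropped") <- n_dropped
  out
}
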