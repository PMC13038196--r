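# Independent oracles used by the tests. Each is a deliberately naive
# implementation (enumeration, closed form, dense integration) that shares
# no code with the package path it checks.

# minimum total cost over every match/no-match combination of a
# rectangular cost matrix where unmatched rows/columns each pay `nonlink`;
# links costing more than `nonlink` are beyond the cutoff and disallowed
brute_force_assignment_cost <- function(cost, nonlink) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf
  rec <- function(i, used_cols, acc) {
    if (acc >= best) return(invisible())
    if (i > nr) {
      best <<- min(best, acc + nonlink * (nc - length(used_cols)))
      return(invisible())
    }
    rec(i + 1L, used_cols, acc + nonlink)
    for (j in seq_len(nc)) {
      if (!(j %in% used_cols) && is.finite(cost[i, j]) &&
          cost[i, j] <= nonlink)
        rec(i + 1L, c(used_cols, j), acc + cost[i, j])
    }
  }
  rec(1L, integer(0), 0)
  best
}

# per-pixel Hessian of a Gaussian-smoothed image by direct dense
# convolution and central finite differences, eigendecomposed with eigen()
oracle_tubeness <- function(img, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(4 * sigma)
  sm <- matrix(0, nr, nc)
  refl <- function(i, n) { i[i < 1] <- 1 - i[i < 1]; i[i > n] <- 2 * n + 1 - i[i > n]; i }
  w <- outer(-r:r, -r:r, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  w <- w / sum(w)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- refl(i + (-r:r), nr); ci <- refl(j + (-r:r), nc)
    sm[i, j] <- sum(w * img[ri, ci])
  }
  resp <- matrix(0, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    hrr <- sm[i + 1, j] - 2 * sm[i, j] + sm[i - 1, j]
    hcc <- sm[i, j + 1] - 2 * sm[i, j] + sm[i, j - 1]
    hrc <- (sm[i + 1, j + 1] - sm[i + 1, j - 1] -
              sm[i - 1, j + 1] + sm[i - 1, j - 1]) / 4
    l1 <- min(eigen(matrix(c(hcc, hrc, hrc, hrr), 2), symmetric = TRUE)$values)
    resp[i, j] <- sigma^2 * max(-l1, 0)
  }
  resp
}

# exhaustive scan of every (interval, region) pair under half-open overlap
brute_force_enrichment <- function(chip, input_signal, regions, q) {
  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  in_any <- function(iv, k) {
    any(vapply(seq_len(nrow(regions)), function(r)
      regions$chrom[r] == iv$chrom[k] &&
        overlaps(iv$start[k], iv$end[k], regions$start[r], regions$end[r]),
      logical(1)))
  }
  inp_vals <- input_signal$value[vapply(seq_len(nrow(input_signal)),
                                        function(k) in_any(input_signal, k),
                                        logical(1))]
  stopifnot(length(inp_vals) > 0)
  n <- length(inp_vals)
  h <- (n - 1) * q / 100
  srt <- sort(inp_vals)
  lo <- floor(h) + 1; hi <- ceiling(h) + 1
  thr <- srt[lo] + (h - floor(h)) * (srt[hi] - srt[lo])
  keep <- vapply(seq_len(nrow(chip)), function(k)
    in_any(chip, k) && chip$value[k] > thr, logical(1))
  list(threshold = thr, kept = chip[keep, c("chrom", "start", "end", "value")])
}

# exact two-sided Mann-Whitney p by enumerating all rank splits
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - na * (na + 1) / 2
  }
  obs <- u_of(seq_len(na))
  splits <- utils::combn(n, na)
  us <- apply(splits, 2, u_of)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}

# classic pooled-variance two-sample t and its two-sided p, from scratch
closed_form_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# one-way ANOVA F from explicit between/within sums of squares
closed_form_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); N <- length(all_v)
  (ssb / (k - 1)) / (ssw / (N - k))
}
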