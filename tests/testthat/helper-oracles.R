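# Independent oracles: deliberately naive re-implementations (double loops,
# enumeration, sort-and-pick) used only to check the package's vectorised
# code paths. They never call package internals.

# per-offset mean of a square matrix by explicit double loop
oracle_diag_means <- function(m) {
  n <- nrow(m)
  out <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    acc <- c()
    for (i in 1:n) for (j in 1:n)
      if (abs(i - j) == d && is.finite(m[i, j])) acc <- c(acc, m[i, j])
    if (length(acc)) out[d + 1] <- mean(acc)
  }
  out
}

# element-wise O/E by explicit loop
oracle_oe_cis <- function(m, expected) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    e <- expected[abs(i - j) + 1]
    if (is.finite(m[i, j]) && is.finite(e) && e != 0)
      out[i, j] <- m[i, j] / e
  }
  out
}

# run-length segmentation of a sign vector by explicit scan
oracle_segments <- function(v) {
  segs <- list()
  cur_start <- NA
  cur_sign <- 0
  n <- length(v)
  for (i in seq_len(n + 1)) {
    s <- if (i > n || !is.finite(v[i])) 0 else sign(v[i])
    if (s != cur_sign) {
      if (cur_sign != 0)
        segs[[length(segs) + 1]] <- c(cur_start - 1, i - 1, cur_sign)
      cur_start <- i
      cur_sign <- s
    }
  }
  if (!length(segs))
    return(data.frame(start = integer(), end = integer(),
                      label = character()))
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1], end = m[, 2],
             label = ifelse(m[, 3] > 0, "A", "B"), stringsAsFactors = FALSE)
}

# bilinear resample of matrix v to S x S, computed pixel by pixel
oracle_bilinear <- function(v, S) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, S, S)
  for (p in 1:S) for (q in 1:S) {
    x <- min(max((p - 0.5) / S * nr - 0.5, 0), nr - 1)
    y <- min(max((q - 0.5) / S * nc - 0.5, 0), nc - 1)
    i0 <- floor(x); j0 <- floor(y)
    i1 <- min(i0 + 1, nr - 1); j1 <- min(j0 + 1, nc - 1)
    fx <- x - i0; fy <- y - j0
    s <- c(v[i0 + 1, j0 + 1], v[i0 + 1, j1 + 1],
           v[i1 + 1, j0 + 1], v[i1 + 1, j1 + 1])
    w <- c((1 - fx) * (1 - fy), (1 - fx) * fy,
           fx * (1 - fy), fx * fy)
    if (any(w > 0 & is.na(s))) next  # stays NA
    out[p, q] <- sum(w[w > 0] * s[w > 0])
  }
  out
}

# per-pixel median by sort-and-middle over a list of equal-size matrices
oracle_median_stack <- function(mats) {
  S1 <- nrow(mats[[1]]); S2 <- ncol(mats[[1]])
  out <- matrix(NA_real_, S1, S2)
  for (i in 1:S1) for (j in 1:S2) {
    vals <- sort(unlist(lapply(mats, function(m) m[i, j])))  # sort drops NA
    k <- length(vals)
    if (k == 0) next
    out[i, j] <- if (k %% 2 == 1) vals[(k + 1) / 2]
                 else (vals[k / 2] + vals[k / 2 + 1]) / 2
  }
  out
}

# filter decision per area, predicate by predicate
oracle_filter_keep <- function(v, dist, context, min_dim, max_zero_frac,
                               max_dist) {
  zf <- sum(is.na(v) | (!is.na(v) & v == 0)) / length(v)
  if (min(nrow(v), ncol(v)) < min_dim) return(FALSE)
  if (zf > max_zero_frac) return(FALSE)
  if (!is.null(max_dist) && context == "cis" && !is.na(dist) &&
      dist > max_dist) return(FALSE)
  TRUE
}

# exact two-sided Wilcoxon signed-rank test by enumeration of the null
# distribution of W+ (dynamic programming over untied integer ranks)
oracle_signrank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  stopifnot(all(r == round(r)))  # oracle requires untied absolute values
  W <- sum(r[d > 0])
  maxw <- n * (n + 1) / 2
  counts <- c(1, rep(0, maxw))  # counts[w+1] = #sign patterns with W+ = w
  for (k in seq_len(n)) {
    rk <- r[k]
    shifted <- c(rep(0, rk), counts)[seq_along(counts)]
    counts <- counts + shifted
  }
  pw <- counts / 2^n
  p_le <- sum(pw[seq_len(W + 1)])
  p_ge <- sum(pw[(W + 1):length(pw)])
  list(W = W, p = min(1, 2 * min(p_le, p_ge)))
}

# convenience: a tiny deterministic two-compartment genome
mini_genome <- function(f = 2, nbins_half = 25L, chroms = 2L,
                        chrom_len = NULL, binsize = 1e5, noise = "none",
                        seed = 7L, ...) {
  if (is.null(chrom_len)) chrom_len <- 2 * nbins_half * binsize
  generate_genome(synthetic_spec(
    chroms = setNames(rep(chrom_len, chroms), paste0("chr", seq_len(chroms))),
    binsize = binsize, f = f, noise = noise, missing_fraction = 0,
    interval_bins = c(nbins_half, nbins_half), seed = seed, ...))
}

# random O/E-like ContactMatrix for property tests
random_cis_cm <- function(n, seed, na_frac = 0) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 3), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (na_frac > 0) {
    idx <- sample(seq_len(n * n), round(na_frac * n * n))
    m[idx] <- NA
  }
  contact_matrix(m, "chr1", 1e5)
}
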