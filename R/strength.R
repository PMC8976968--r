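# Compartment strength: mean within-compartment O/E divided by mean
# between-compartment O/E, the denominator taken over the edge-cropped AB
# panel. Computed per chromosome so conditions can be compared with paired
# statistics.

STRENGTH_TYPES <- c("A_short", "B_short", "A_long", "B_long", "combined")

#' Crop the edges of a panel
#'
#' Removes `k = floor(crop_fraction * S)` pixels from each of the four sides
#' of an `S x S` panel, returning the central `(S-2k) x (S-2k)` block. The
#' crop removes residual within-compartment interactions near the edges of
#' the AB panel before the strength denominator is taken.
#'
#' @param panel `S x S` numeric matrix.
#' @param crop_fraction Real in `[0, 0.5)`; 0 is the identity.
#' @return The central subarray.
#' @export
crop_center <- function(panel, crop_fraction = 0.25) {
  if (!is.matrix(panel) || nrow(panel) != ncol(panel))
    stop_validation("'panel' must be a square matrix")
  .assert_scalar_num(crop_fraction, "crop_fraction", lo = 0)
  if (crop_fraction >= 0.5) stop_validation("'crop_fraction' must be < 0.5")
  S <- nrow(panel)
  k <- floor(crop_fraction * S)
  if (S - 2 * k < 1) stop_validation("crop leaves an empty panel")
  panel[(k + 1):(S - k), (k + 1):(S - k), drop = FALSE]
}

#' Compartment strength of one chromosome
#'
#' For each within type (`A_short`, `B_short`, `A_long`, `B_long`):
#' `strength = mean(finite pixels of the panel) / mean(finite pixels of the
#' cropped AB panel)`. The `combined` strength pools the pixels of all four
#' within panels (so panels weigh by their finite-pixel counts) over the
#' same denominator. Strength is `NA` where the numerator panel or the AB
#' panel has no finite pixel, or the cropped-AB mean is 0.
#'
#' @param panels Named list of `S x S` matrices with entries `A_short`,
#'   `B_short`, `A_long`, `B_long`, `AB` (missing entries allowed), or a
#'   `Pentad` in cis mode.
#' @param crop_fraction Passed to [crop_center()].
#' @return Named numeric vector over
#'   `A_short, B_short, A_long, B_long, combined`.
#' @export
compartment_strength <- function(panels, crop_fraction = 0.25) {
  if (inherits(panels, "Pentad"))
    panels <- lapply(panels$panels, `[[`, "values")
  if (is.null(panels$AB))
    stop_validation("an 'AB' panel is required for the strength denominator")
  ab <- crop_center(panels$AB, crop_fraction)
  ab_fin <- ab[is.finite(ab)]
  denom <- if (length(ab_fin)) mean(ab_fin) else NA_real_
  if (!is.na(denom) && denom == 0) {
    warning("cropped AB panel has mean 0; strengths undefined", call. = FALSE)
    denom <- NA_real_
  }
  within <- c("A_short", "B_short", "A_long", "B_long")
  out <- setNames(rep(NA_real_, 5L), STRENGTH_TYPES)
  pooled <- numeric(0)
  for (t in within) {
    p <- panels[[t]]
    fin <- if (is.null(p)) numeric(0) else p[is.finite(p)]
    pooled <- c(pooled, fin)
    if (length(fin) && !is.na(denom)) out[t] <- mean(fin) / denom
  }
  if (length(pooled) && !is.na(denom))
    out["combined"] <- mean(pooled) / denom
  out
}

#' Per-chromosome compartment strength table
#'
#' Builds a per-chromosome pentad (areas are not pooled across chromosomes)
#' and one strength row per chromosome, using the same filter settings as
#' the genome-wide pentad.
#'
#' @param oe_maps Named list of cis O/E [contact_matrix()] objects, one per
#'   chromosome.
#' @param intervals Named list of [segment_signal()] data.frames.
#' @param settings A [pentad_settings()] object.
#' @return A `StrengthTable` data.frame: `chrom` plus one column per type in
#'   `A_short, B_short, A_long, B_long, combined`; `NA` where no areas
#'   survive.
#' @export
strength_genome <- function(oe_maps, intervals, settings = pentad_settings()) {
  chroms <- intersect(names(oe_maps), names(intervals))
  if (!length(chroms)) stop_validation("no chromosome shared between inputs")
  rows <- lapply(chroms, function(ch) {
    p <- withCallingHandlers(
      build_pentad(oe_maps[ch], intervals[ch], mode = "cis",
                   settings = settings),
      warning = function(w) invokeRestart("muffleWarning"))
    compartment_strength(p, settings$crop_fraction)
  })
  tab <- data.frame(chrom = chroms, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab, crop_fraction = settings$crop_fraction,
            class = c("StrengthTable", "data.frame"))
}

#' Write / read a strength table as TSV
#'
#' @param table A [strength_genome()] result.
#' @param path File path.
#' @return `path` (write) or a `StrengthTable` (read).
#' @export
write_strength_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_strength_table
#' @export
read_strength_table <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", STRENGTH_TYPES)
  if (!all(need %in% names(tab)))
    stop_validation("strength table must have columns: %s",
                    paste(need, collapse = ", "))
  structure(tab, class = c("StrengthTable", "data.frame"))
}

# Two-sided paired signed-rank test on the nonzero differences d.
# Exact permutation null for n < 26, enumerated by dynamic programming over
# doubled ranks (doubling makes average ranks integral, so the exact route
# also covers tied |d|, where stats::wilcox.test would fall back to the
# normal approximation); normal approximation with tie and continuity
# corrections otherwise.
.signrank_test <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n < 26) {
    r2 <- as.integer(round(2 * r))
    counts <- c(1, rep(0, sum(r2)))  # counts[w+1]: #sign patterns, W2 = w
    for (rk in r2)
      counts <- counts + c(rep(0, rk), counts)[seq_along(counts)]
    pw <- counts / 2^n
    w2 <- as.integer(round(2 * W))
    p <- min(1, 2 * min(sum(pw[seq_len(w2 + 1)]),
                        sum(pw[(w2 + 1):length(pw)])))
  } else {
    mu <- n * (n + 1) / 4
    nties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(nties^3 - nties) / 48)
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
  list(statistic = W, p_value = p)
}

# significance tiers as conventionally annotated on the strength box plots
.significance_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else
    if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' Compare two conditions with the Wilcoxon signed-rank test
#'
#' For each area type, a two-sided paired Wilcoxon signed-rank test on
#' per-chromosome strengths over the chromosomes with finite values in both
#' tables. Zero differences are dropped before ranking (classical
#' treatment); the exact distribution is used for fewer than 26 zero-free
#' pairs, the normal approximation with continuity correction otherwise.
#' With all differences zero, p is reported as 1.
#'
#' @param table_1,table_2 Two `StrengthTable`s (see [strength_genome()]).
#' @return data.frame with one row per type: `type`, `n` (pairs entering the
#'   test after zero-dropping), `statistic` (V, sum of positive ranks),
#'   `p_value`, `significance` tier (`****` p <= 1e-4, `***` p <= 1e-3,
#'   `**` p <= 0.01, `*` p <= 0.05, `ns` otherwise).
#' @export
compare_conditions <- function(table_1, table_2) {
  shared <- intersect(table_1$chrom, table_2$chrom)
  if (!length(shared))
    stop_validation("the two strength tables share no chromosome")
  i1 <- match(shared, table_1$chrom)
  i2 <- match(shared, table_2$chrom)
  rows <- lapply(STRENGTH_TYPES, function(t) {
    x <- table_1[[t]][i1]
    y <- table_2[[t]][i2]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 6L)
      warning(sprintf(
        "type %s: only %d finite pairs; exact p-values are coarse below 6",
        t, length(x)), call. = FALSE)
    d <- x - y
    nz <- sum(d != 0)
    if (length(d) == 0L || nz == 0L)
      return(data.frame(type = t, n = nz, statistic = NA_real_, p_value = 1,
                        significance = "ns", stringsAsFactors = FALSE))
    wt <- .signrank_test(d[d != 0])
    data.frame(type = t, n = nz, statistic = wt$statistic,
               p_value = wt$p_value,
               significance = .significance_tier(wt$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("pentad_comparison", "data.frame"))
}

#' @rdname compare_conditions
#' @param report A `compare_conditions()` result.
#' @param path File path for the TSV report.
#' @export
write_comparison <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
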