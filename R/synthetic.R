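# Seeded synthetic Hi-C genomes with planted compartment structure, for
# fixtures, null calibration and parameter recovery.
#
# Cis entry (i,j) = depth * (|i-j|+1)^(-alpha) * m(i,j), with m = f when
# bins i and j share the planted label and 1/f otherwise; trans entry =
# depth_trans * m(i,j). Relative to the generator's own decay profile the
# planted O/E is therefore exactly {f, 1/f}, making f^2 the analytic
# combined-strength target. (The *empirical* per-diagonal expected partially
# absorbs the contrast at short offsets, where most pairs share a label;
# recovery tests hence use the known profile, see true_expected_cis().)

#' Specification of a synthetic compartment genome
#'
#' @param chroms Named numeric vector of chromosome lengths in bp.
#' @param binsize Bin size in bp.
#' @param f Planted contrast `>= 1`: within-compartment contact multiplier
#'   (between-compartment multiplier is `1/f`); `f = 1` is the structureless
#'   null.
#' @param alpha Distance-decay exponent: expected cis contacts fall off as
#'   `(d + 1)^(-alpha)` in bins.
#' @param noise `"none"` (deterministic real-valued counts) or `"poisson"`
#'   (each count replaced by a Poisson draw with that mean).
#' @param depth Cis sequencing-depth scale: the expected count at distance 0.
#' @param depth_trans Trans depth scale (expected trans count per bin pair).
#' @param missing_fraction Fraction of bins per chromosome blanked to
#'   missing (their balancing weight is `NA`, mimicking bins masked during
#'   matrix balancing), in `[0, 1)`.
#' @param interval_bins Optional integer vector of interval lengths in bins,
#'   recycled along each chromosome (fixed layout); when `NULL`, lengths are
#'   sampled uniformly from `interval_range`.
#' @param interval_range Length-2 integer range (bins) for sampled interval
#'   lengths.
#' @param seed Integer seed; identical specs give identical genomes.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(chroms = setNames(rep(50e6, 4), paste0("chr", 1:4)),
                           binsize = 100e3, f = 2, alpha = 1,
                           noise = c("poisson", "none"), depth = 1000,
                           depth_trans = 10, missing_fraction = 0.02,
                           interval_bins = NULL, interval_range = c(5L, 15L),
                           seed = 1L) {
  noise <- match.arg(noise)
  .assert_scalar_num(f, "f", lo = 1)
  .assert_scalar_num(alpha, "alpha", lo = 1e-9)
  .assert_scalar_num(depth, "depth", lo = 1e-9)
  .assert_scalar_num(depth_trans, "depth_trans", lo = 1e-9)
  .assert_scalar_num(missing_fraction, "missing_fraction", lo = 0, hi = 1 - 1e-9)
  bins <- genome_bins(chroms, binsize)  # validates chroms/binsize
  if (!is.null(interval_bins)) {
    if (any(interval_bins < 1) || any(interval_bins %% 1 != 0))
      stop_validation("'interval_bins' must be positive whole bin counts")
  }
  structure(list(chroms = chroms, binsize = binsize, f = f, alpha = alpha,
                 noise = noise, depth = depth, depth_trans = depth_trans,
                 missing_fraction = missing_fraction,
                 interval_bins = interval_bins,
                 interval_range = as.integer(interval_range),
                 seed = as.integer(seed), bins = bins),
            class = "SyntheticSpec")
}

# alternating A/B layout of one chromosome; returns per-bin label vector
.plant_layout <- function(spec, nbins) {
  lens <- integer(0)
  if (!is.null(spec$interval_bins)) {
    while (sum(lens) < nbins)
      lens <- c(lens, spec$interval_bins)
  } else {
    while (sum(lens) < nbins)
      lens <- c(lens, sample(spec$interval_range[1]:spec$interval_range[2], 1L))
  }
  lens[length(lens)] <- lens[length(lens)] - (sum(lens) - nbins)
  lens <- lens[lens > 0]
  rep(rep_len(c("A", "B"), length(lens)), lens)
}

#' Generate a synthetic compartment genome
#'
#' Builds, deterministically from the spec's seed, all cis matrices, all
#' trans pair matrices, the compartment-signal tracks (+1 on A bins, -1 on B
#' bins) and a ground-truth record. Blanked bins carry `NA` rows/columns in
#' the retained matrices and an `NA` balancing weight in written containers;
#' all other bins get unit weight, so balanced and raw reads agree up to the
#' missing mask.
#'
#' @param spec A [synthetic_spec()].
#' @return A `SyntheticGenome`: `spec`, `bins`, per-chromosome `labels`,
#'   `intervals`, `tracks`, `weights`, `cis` matrices, `trans` matrices
#'   (named `"chrA|chrB"`).
#' @export
generate_genome <- function(spec) {
  if (!inherits(spec, "SyntheticSpec")) stop_validation("not a SyntheticSpec")
  set.seed(spec$seed)
  bins <- spec$bins
  chroms <- names(spec$chroms)
  labels <- list(); tracks <- list(); weights <- list()
  cis <- list(); intervals <- list()

  for (ch in chroms) {
    n <- bins$nbins[[ch]]
    lab <- .plant_layout(spec, n)
    labels[[ch]] <- lab
    tracks[[ch]] <- binned_track(ch, ifelse(lab == "A", 1, -1), spec$binsize)
    intervals[[ch]] <- segment_signal(tracks[[ch]])

    d <- abs(.row(c(n, n)) - .col(c(n, n)))
    m <- ifelse(outer(lab, lab, `==`), spec$f, 1 / spec$f)
    vals <- spec$depth * (d + 1)^(-spec$alpha) * m
    if (spec$noise == "poisson") {
      ut <- upper.tri(vals, diag = TRUE)
      vals[ut] <- stats::rpois(sum(ut), vals[ut])
      vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
    }
    w <- rep(1, n)
    nblank <- floor(spec$missing_fraction * n)
    if (nblank > 0) {
      blank <- sample.int(n, nblank)
      w[blank] <- NA_real_
      vals[blank, ] <- NA_real_
      vals[, blank] <- NA_real_
    }
    weights[[ch]] <- w
    cis[[ch]] <- contact_matrix(vals, ch, spec$binsize, balanced = TRUE)
  }

  trans <- list()
  if (length(chroms) > 1L) {
    for (i in seq_len(length(chroms) - 1L)) {
      for (j in (i + 1L):length(chroms)) {
        c1 <- chroms[i]; c2 <- chroms[j]
        m <- ifelse(outer(labels[[c1]], labels[[c2]], `==`),
                    spec$f, 1 / spec$f)
        vals <- spec$depth_trans * m
        if (spec$noise == "poisson")
          vals[] <- stats::rpois(length(vals), vals)
        vals[is.na(weights[[c1]]), ] <- NA_real_
        vals[, is.na(weights[[c2]])] <- NA_real_
        trans[[paste(c1, c2, sep = "|")]] <-
          contact_matrix(vals, c(c1, c2), spec$binsize, balanced = TRUE)
      }
    }
  }

  structure(list(spec = spec, bins = bins, labels = labels,
                 intervals = intervals, tracks = tracks, weights = weights,
                 cis = cis, trans = trans),
            class = "SyntheticGenome")
}

#' True expected profile of a synthetic chromosome
#'
#' The decay the generator actually used: `depth * (d + 1)^(-alpha)`.
#' Relative to this profile the planted O/E is exactly `f` within and `1/f`
#' between compartments.
#'
#' @param genome A [generate_genome()] result.
#' @param chrom Chromosome name.
#' @return An `ExpectedProfile` (see [expected_cis()]).
#' @export
true_expected_cis <- function(genome, chrom) {
  n <- genome$bins$nbins[[chrom]]
  structure(list(chrom = chrom,
                 values = genome$spec$depth * (seq_len(n))^(-genome$spec$alpha)),
            class = "ExpectedProfile")
}

#' O/E maps of a synthetic genome
#'
#' @param genome A [generate_genome()] result.
#' @param expected `"true"` divides by the generator's known decay (the
#'   planted-contrast scale; use for parameter recovery), `"empirical"` by
#'   the per-diagonal mean of the generated matrix (what the pipeline does
#'   on real data).
#' @return List with `cis` and `trans` named lists of O/E
#'   [contact_matrix()] objects.
#' @export
synthetic_oe <- function(genome, expected = c("true", "empirical")) {
  expected <- match.arg(expected)
  cis <- lapply(names(genome$cis), function(ch) {
    e <- if (expected == "true") true_expected_cis(genome, ch)
         else expected_cis(genome$cis[[ch]])
    oe_cis(genome$cis[[ch]], e)
  })
  names(cis) <- names(genome$cis)
  tr <- lapply(genome$trans, function(cm) {
    if (expected == "true") {
      out <- cm
      out$values <- cm$values / genome$spec$depth_trans
      out$values[!is.finite(out$values)] <- NA_real_
      out
    } else oe_trans(cm)
  })
  list(cis = cis, trans = tr)
}

# merge equal-value runs of a track into bedGraph records
.track_to_bedgraph <- function(track, chrlen) {
  v <- track$values
  bs <- track$binsize
  r <- rle(ifelse(is.na(v), NA_real_, v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !is.na(r$values)
  data.frame(chrom = track$chrom,
             start = starts[keep] * bs,
             end = pmin(ends[keep] * bs, chrlen),
             value = r$values[keep])
}

#' Write a synthetic genome as cooler + bedGraph fixture files
#'
#' Emits `<prefix>.cool` (single-resolution cooler with unit balancing
#' weights, `NA` at blanked bins), `<prefix>.bedGraph` (the compartment
#' signal with constant runs merged) and `<prefix>.truth.json` (planted
#' intervals and generator parameters). [read_contact_matrix()] /
#' [read_compartment_signal()] round-trip both exactly.
#'
#' @param genome A [generate_genome()] result.
#' @param prefix Output path prefix.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(genome, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  bins <- genome$bins
  off <- .bin_offsets(bins)
  chroms <- names(bins$chroms)

  pix <- vector("list", 0)
  for (ch in chroms) {
    v <- genome$cis[[ch]]$values
    idx <- which(upper.tri(v, diag = TRUE) & !is.na(v) & v != 0,
                 arr.ind = TRUE)
    if (nrow(idx))
      pix[[length(pix) + 1L]] <- data.frame(
        bin1_id = off[[ch]] + idx[, 1] - 1L,
        bin2_id = off[[ch]] + idx[, 2] - 1L,
        count = v[idx])
  }
  for (pair in names(genome$trans)) {
    chs <- strsplit(pair, "|", fixed = TRUE)[[1]]
    v <- genome$trans[[pair]]$values
    idx <- which(!is.na(v) & v != 0, arr.ind = TRUE)
    if (nrow(idx))
      pix[[length(pix) + 1L]] <- data.frame(
        bin1_id = off[[chs[1]]] + idx[, 1] - 1L,
        bin2_id = off[[chs[2]]] + idx[, 2] - 1L,
        count = v[idx])
  }
  pixels <- do.call(rbind, pix)
  pixels <- pixels[order(pixels$bin1_id, pixels$bin2_id), ]

  cool <- paste0(prefix, ".cool")
  cooler_create(cool, bins$chroms, bins$binsize, pixels,
                weights = unlist(genome$weights, use.names = FALSE))

  bg <- do.call(rbind, lapply(chroms, function(ch)
    .track_to_bedgraph(genome$tracks[[ch]], bins$chroms[[ch]])))
  bedgraph <- paste0(prefix, ".bedGraph")
  utils::write.table(format(bg, scientific = FALSE, trim = TRUE), bedgraph,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  truth <- paste0(prefix, ".truth.json")
  sp <- genome$spec
  jsonlite::write_json(list(
    chroms = as.list(sp$chroms), binsize = sp$binsize, f = sp$f,
    alpha = sp$alpha, noise = sp$noise, depth = sp$depth,
    depth_trans = sp$depth_trans, missing_fraction = sp$missing_fraction,
    seed = sp$seed,
    intervals = genome$intervals,
    blanked_bins = lapply(genome$weights, function(w) which(is.na(w)) - 1L)),
    truth, auto_unbox = TRUE, na = "null", digits = NA)

  invisible(c(cool = cool, bedgraph = bedgraph, truth = truth))
}
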