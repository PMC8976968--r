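# Input layer: bin grids, contact matrices, compartment signal tracks.
# Coordinates are 0-based half-open everywhere internally (the native
# convention of both bedGraph and cooler).

#' Define a genome bin grid
#'
#' @param chroms Named numeric vector of chromosome lengths in bp.
#' @param binsize Bin size in bp.
#' @return A `GenomeBins` object: chromosome lengths, bin size, and the
#'   per-chromosome bin count `ceiling(length / binsize)`.
#' @export
genome_bins <- function(chroms, binsize) {
  .assert_scalar_num(binsize, "binsize", lo = 1)
  if (is.null(names(chroms)) || any(!nzchar(names(chroms))))
    stop_validation("'chroms' must be a named vector of chromosome lengths")
  if (any(!is.finite(chroms)) || any(chroms <= 0))
    stop_validation("chromosome lengths must be positive")
  structure(list(chroms = chroms, binsize = as.numeric(binsize),
                 nbins = setNames(as.integer(ceiling(chroms / binsize)),
                                  names(chroms))),
            class = "GenomeBins")
}

#' @export
print.GenomeBins <- function(x, ...) {
  cat(sprintf("GenomeBins: %d chromosome(s) at %s bp bins (%d bins total)\n",
              length(x$chroms), format(x$binsize, big.mark = ",", scientific = FALSE),
              sum(x$nbins)))
  invisible(x)
}

# 0-based global bin offset of each chromosome's first bin
.bin_offsets <- function(bins) {
  setNames(c(0L, cumsum(bins$nbins))[seq_along(bins$nbins)], names(bins$nbins))
}

#' Construct a contact matrix object
#'
#' A thin container for a dense cis (square) or trans (rectangular) contact
#' matrix with its genomic context. `NA` entries are missing (e.g. bins
#' masked during balancing).
#'
#' @param values Numeric matrix; finite entries must be `>= 0`.
#' @param chroms Character vector: one chromosome name (cis) or two (trans).
#' @param binsize Bin size in bp.
#' @param balanced Logical: are values balanced (`TRUE`) or raw counts?
#' @return A `ContactMatrix` object.
#' @export
contact_matrix <- function(values, chroms, binsize, balanced = FALSE) {
  if (!is.matrix(values)) stop_validation("'values' must be a matrix")
  if (!length(chroms) %in% 1:2)
    stop_validation("'chroms' must name one (cis) or two (trans) chromosomes")
  fin <- values[is.finite(values)]
  if (length(fin) && min(fin) < 0)
    stop_validation("contact values must be non-negative")
  if (length(chroms) == 1L && nrow(values) != ncol(values))
    stop_validation("cis contact matrix must be square")
  structure(list(values = values, chroms = as.character(chroms),
                 binsize = as.numeric(binsize), balanced = isTRUE(balanced)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix %s [%d x %d] @ %s bp (%s)\n",
              paste(x$chroms, collapse = " x "),
              nrow(x$values), ncol(x$values),
              format(x$binsize, big.mark = ",", scientific = FALSE),
              if (x$balanced) "balanced" else "raw"))
  invisible(x)
}

is_cis <- function(x) length(x$chroms) == 1L

#' Construct a binned signal track
#'
#' @param chrom Chromosome name.
#' @param values One numeric value per bin; `NA` marks bins without a
#'   compartment call. The sign encodes membership: positive = A,
#'   negative = B.
#' @param binsize Bin size in bp.
#' @return A `BinnedTrack` object.
#' @export
binned_track <- function(chrom, values, binsize) {
  structure(list(chrom = as.character(chrom), values = as.numeric(values),
                 binsize = as.numeric(binsize)),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack %s: %d bins @ %s bp (%.1f%% missing)\n",
              x$chrom, length(x$values), format(x$binsize, big.mark = ",", scientific = FALSE),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read a dense contact matrix from a cooler container
#'
#' @param path Path to a `.cool` / `.mcool` container.
#' @param region Character vector: one chromosome (cis) or two (trans).
#' @param use_balanced `NA` (default) selects balanced values when balancing
#'   weights are stored and falls back to raw counts (with a message)
#'   otherwise; `TRUE` requires weights and errors without them; `FALSE`
#'   always reads raw counts. Balanced matrices carry `NA` at masked bins.
#' @param resolution Bin size selecting a resolution of a multi-resolution
#'   container; mandatory for `.mcool` inputs (no auto-selection).
#' @return A [contact_matrix()] object.
#' @export
read_contact_matrix <- function(path, region, use_balanced = NA,
                                resolution = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (!length(region) %in% 1:2)
    stop_validation("'region' must name one or two chromosomes")
  info <- cooler_info(path, resolution)
  if (isTRUE(info$multires) && is.null(info$binsize))
    stop_validation(
      "multi-resolution container: pass 'resolution' (available: %s)",
      paste(info$resolutions, collapse = ", "))
  missing_chroms <- setdiff(region, info$chroms$name)
  if (length(missing_chroms))
    stop_validation("chromosome(s) not in container: %s",
                    paste(missing_chroms, collapse = ", "))
  balanced <- use_balanced
  if (is.na(balanced)) {
    balanced <- info$has_weights
    if (!balanced)
      message("no balancing weights stored; reading raw counts")
  } else if (isTRUE(balanced) && !info$has_weights) {
    stop_validation("balanced values requested but container stores no weights")
  }
  vals <- .cooler_dump(path, region[1],
                       if (length(region) == 2L) region[2] else NULL,
                       balanced = balanced, resolution = resolution)
  contact_matrix(vals, region, info$binsize, balanced = balanced)
}

#' Bin grid of a cooler container
#'
#' @inheritParams read_contact_matrix
#' @return A [genome_bins()] object matching the container.
#' @export
cooler_genome_bins <- function(path, resolution = NULL) {
  info <- cooler_info(path, resolution)
  if (isTRUE(info$multires) && is.null(info$binsize))
    stop_validation(
      "multi-resolution container: pass 'resolution' (available: %s)",
      paste(info$resolutions, collapse = ", "))
  genome_bins(setNames(info$chroms$length, info$chroms$name), info$binsize)
}

#' Read a compartment signal from a bedGraph file
#'
#' Expands bedGraph records (4 columns, 0-based half-open; an optional
#' `track`/`#`/`browser` header line is skipped) onto the bin grid. A record
#' spanning k bins contributes k per-bin values. Bins without a record, or
#' whose value is exactly 0 or non-finite, are marked missing: the sign of
#' the signal encodes the compartment and is undefined at 0.
#'
#' @param path Path to the bedGraph file.
#' @param bins A [genome_bins()] object defining the target grid.
#' @return Named list of [binned_track()] objects, one per chromosome present
#'   in both the file and `bins`. File chromosomes absent from `bins` are
#'   skipped with a warning.
#' @export
read_compartment_signal <- function(path, bins) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (!inherits(bins, "GenomeBins"))
    stop_validation("'bins' must be a GenomeBins object")
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && grepl("^(track|browser|#)", first)) 1L else 0L
  bg <- data.table::fread(path, skip = skip, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1, numeric = 2:4))
  if (!nrow(bg)) stop_validation("bedGraph file has no records: %s", path)
  bg$line <- seq_len(nrow(bg)) + skip
  bs <- bins$binsize

  extra <- setdiff(unique(bg$chrom), names(bins$chroms))
  if (length(extra)) {
    warning(sprintf("skipping bedGraph chromosome(s) absent from bin grid: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    bg <- bg[!bg$chrom %in% extra, ]
  }
  if (!nrow(bg))
    stop_validation("no bedGraph chromosome matches the bin grid")

  tracks <- list()
  for (ch in intersect(names(bins$chroms), unique(bg$chrom))) {
    rec <- bg[bg$chrom == ch, ]
    rec <- rec[order(rec$start), ]
    n <- bins$nbins[[ch]]
    chrlen <- bins$chroms[[ch]]
    aligned <- rec$start %% bs == 0 &
      (rec$end %% bs == 0 | rec$end == chrlen) & rec$end > rec$start
    if (any(!aligned)) {
      # distinguish a wholesale bin-size mismatch from a stray record
      gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
      grid <- Reduce(gcd2, c(rec$start, rec$end[rec$end != chrlen]))
      if (grid > 0 && grid %% bs != 0)
        stop_validation(
          "bin-size mismatch: matrix bins at %s bp, signal records align to a %s bp grid",
          format(bs, scientific = FALSE), format(grid, scientific = FALSE))
      stop_validation(
        "bedGraph line %d: span [%s, %s) on %s is not aligned to %s bp bins",
        rec$line[!aligned][1],
        format(rec$start[!aligned][1], scientific = FALSE),
        format(rec$end[!aligned][1], scientific = FALSE), ch,
        format(bs, scientific = FALSE))
    }
    if (nrow(rec) > 1L && any(rec$start[-1] < rec$end[-nrow(rec)]))
      stop_validation("overlapping bedGraph records on %s (near line %d)",
                      ch, rec$line[which(rec$start[-1] < rec$end[-nrow(rec)])[1] + 1L])
    v <- rep(NA_real_, n)
    b0 <- rec$start %/% bs
    b1 <- pmin(ceiling(rec$end / bs), n) - 1L  # inclusive last bin index
    keep <- is.finite(rec$value) & rec$value != 0
    for (k in which(keep)) v[(b0[k]:b1[k]) + 1L] <- rec$value[k]
    tracks[[ch]] <- binned_track(ch, v, bs)
  }
  tracks
}

#' Check that a contact matrix and a compartment signal share a bin grid
#'
#' @param matrix_bins [genome_bins()] of the contact container.
#' @param tracks Named list of [binned_track()] objects.
#' @return A validation report: shared chromosomes, per-chromosome
#'   missing-bin fraction of the signal, and the common bin size.
#' @export
validate_inputs <- function(matrix_bins, tracks) {
  if (!inherits(matrix_bins, "GenomeBins"))
    stop_validation("'matrix_bins' must be a GenomeBins object")
  if (!length(tracks)) stop_validation("no signal tracks given")
  track_bs <- unique(vapply(tracks, `[[`, numeric(1), "binsize"))
  if (length(track_bs) != 1L || track_bs != matrix_bins$binsize)
    stop_validation("bin-size mismatch: matrix at %s bp, signal at %s bp",
                    format(matrix_bins$binsize, scientific = FALSE),
                    paste(format(track_bs, scientific = FALSE),
                          collapse = "/"))
  shared <- intersect(names(matrix_bins$chroms), names(tracks))
  if (!length(shared))
    stop_validation("matrix and signal share no chromosome")
  skipped <- setdiff(names(tracks), shared)
  if (length(skipped))
    warning(sprintf("signal chromosome(s) not in matrix, ignored: %s",
                    paste(skipped, collapse = ", ")), call. = FALSE)
  for (ch in shared)
    if (length(tracks[[ch]]$values) != matrix_bins$nbins[[ch]])
      stop_validation("track %s has %d bins, expected %d",
                      ch, length(tracks[[ch]]$values),
                      matrix_bins$nbins[[ch]])
  structure(list(
    shared_chroms = shared,
    skipped_chroms = skipped,
    binsize = matrix_bins$binsize,
    missing_fraction = vapply(
      tracks[shared], function(t) mean(is.na(t$values)), numeric(1))),
    class = "pentad_validation_report")
}

#' @export
print.pentad_validation_report <- function(x, ...) {
  cat(sprintf("Inputs OK: %d shared chromosome(s) at %s bp\n",
              length(x$shared_chroms), format(x$binsize, big.mark = ",", scientific = FALSE)))
  for (ch in x$shared_chroms)
    cat(sprintf("  %s: %.1f%% of signal bins missing\n",
                ch, 100 * x$missing_fraction[[ch]]))
  invisible(x)
}
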