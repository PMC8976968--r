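# Low-level cooler (HDF5) container access.
#
# There are no HDF5 bindings among the package's R dependencies, so the byte
# work is delegated to a bundled Python helper (inst/python/cooler_io.py,
# requires numpy + h5py). Matrices cross the process boundary as little-endian
# binary blobs in temporary files; metadata as JSON.

.python_bin <- function() {
  opt <- getOption("hicpentad.python")
  if (!is.null(opt)) return(opt)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop_input("no 'python' interpreter found on PATH (needed for cooler I/O)")
}

.cooler_script <- function() {
  p <- system.file("python", "cooler_io.py", package = "hicpentad")
  if (!nzchar(p)) stop_input("bundled cooler_io.py not found")
  p
}

# Run a helper command; raise a validation error carrying the helper's
# diagnostic on non-zero exit.
.cooler_call <- function(args) {
  out <- suppressWarnings(
    system2(.python_bin(), c(shQuote(.cooler_script()), shQuote(args)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    msg <- sub("^ERROR: ", "", paste(out, collapse = " "))
    stop_validation("cooler backend: %s", msg)
  }
  out
}

#' Inspect a cooler container
#'
#' Reads container-level metadata from a single-resolution `.cool` file or a
#' multi-resolution `.mcool` file without loading any matrix data.
#'
#' @param path Path to a cooler container.
#' @param resolution Bin size in bp selecting one resolution of a
#'   multi-resolution container; ignored (may be `NULL`) for single-resolution
#'   files.
#' @return A list with elements `binsize`, `chroms` (data.frame of `name`,
#'   `length`), `nbins`, `has_weights`, `multires` and (for multi-resolution
#'   containers) `resolutions`.
#' @export
cooler_info <- function(path, resolution = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  args <- c("info", path)
  if (!is.null(resolution)) args <- c(args, format(resolution, scientific = FALSE))
  info <- jsonlite::fromJSON(paste(.cooler_call(args), collapse = ""))
  if (isTRUE(info$multires) && is.null(info$binsize)) return(info)
  info$chroms <- as.data.frame(info$chroms)
  info
}

# Dense matrix for a region; NaN (mapped to NA) marks masked bins of a
# balanced matrix. Row-major on disk.
.cooler_dump <- function(path, chrom1, chrom2 = NULL, balanced = TRUE,
                         resolution = NULL) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp), add = TRUE)
  res <- if (is.null(resolution)) "-" else format(resolution, scientific = FALSE)
  c2 <- if (is.null(chrom2)) "-" else chrom2
  .cooler_call(c("dump", path, res, chrom1, c2,
                 if (balanced) "1" else "0", tmp))
  con <- file(tmp, "rb")
  on.exit(close(con), add = TRUE, after = FALSE)
  dims <- readBin(con, "integer", n = 2L, size = 8L, endian = "little")
  vals <- readBin(con, "double", n = dims[1] * dims[2], endian = "little")
  vals[is.nan(vals)] <- NA_real_
  matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

#' Write a single-resolution cooler container
#'
#' Creates a `.cool` file from an upper-triangle pixel table. Used by the
#' synthetic-data generator; exported because it is handy for building small
#' test containers.
#'
#' @param path Output file path.
#' @param chroms Named numeric vector of chromosome lengths in bp, in the
#'   desired container order.
#' @param binsize Bin size in bp.
#' @param pixels data.frame with columns `bin1_id`, `bin2_id` (0-based global
#'   bin ids, `bin1_id <= bin2_id`) and `count`.
#' @param weights Optional numeric vector of balancing weights, one per bin
#'   (`NA` marks masked bins). When given, balanced reads multiply counts by
#'   the two bin weights.
#' @return `path`, invisibly.
#' @export
cooler_create <- function(path, chroms, binsize, pixels, weights = NULL) {
  if (is.null(names(chroms)) || any(!nzchar(names(chroms))))
    stop_validation("'chroms' must be a named vector of lengths")
  .assert_scalar_num(binsize, "binsize", lo = 1)
  need <- c("bin1_id", "bin2_id", "count")
  if (!all(need %in% names(pixels)))
    stop_validation("'pixels' must have columns bin1_id, bin2_id, count")
  if (any(pixels$bin2_id < pixels$bin1_id))
    stop_validation("pixels must satisfy bin1_id <= bin2_id")

  meta <- list(
    binsize = binsize,
    chroms = lapply(seq_along(chroms), function(i)
      list(name = names(chroms)[i], length = unname(chroms[i]))))
  if (!is.null(weights)) meta$weights <- as.numeric(weights)
  meta_path <- tempfile(fileext = ".json")
  pix_path <- tempfile(fileext = ".bin")
  on.exit(unlink(c(meta_path, pix_path)), add = TRUE)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, na = "null",
                              digits = NA), meta_path)
  con <- file(pix_path, "wb")
  writeBin(nrow(pixels), con, size = 8L, endian = "little")
  writeBin(as.integer(pixels$bin1_id), con, size = 8L, endian = "little")
  writeBin(as.integer(pixels$bin2_id), con, size = 8L, endian = "little")
  writeBin(as.double(pixels$count), con, endian = "little")
  close(con)
  .cooler_call(c("create", path, meta_path, pix_path))
  invisible(path)
}
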