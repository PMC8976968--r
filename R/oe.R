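# Observed-over-expected transform. Cis expectation is the per-diagonal
# arithmetic mean of the same chromosome's matrix (no pooling, no smoothing);
# trans expectation is the scalar mean of the chromosome-pair matrix. Means
# ignore missing entries; division by an expected value of 0 yields missing.

# per-offset means of a square matrix, NA-aware; returns length-n vector
.diag_means <- function(m) {
  n <- nrow(m)
  d <- abs(.row(dim(m)) - .col(dim(m)))
  fin <- is.finite(m)
  v <- m
  v[!fin] <- 0
  sums <- rowsum(as.vector(v), as.vector(d))
  cnts <- rowsum(as.numeric(fin), as.vector(d))
  out <- rep(NA_real_, n)
  idx <- as.integer(rownames(sums)) + 1L
  out[idx] <- ifelse(cnts[, 1] > 0, sums[, 1] / cnts[, 1], NA_real_)
  out
}

#' Expected cis contacts by genomic distance
#'
#' Entry `d+1` of the profile is the arithmetic mean of all finite matrix
#' entries at bin offset `|i - j| = d`; offsets with no finite entry carry
#' `NA`.
#'
#' @param matrix A cis [contact_matrix()].
#' @return An `ExpectedProfile`: chromosome name plus one mean per offset.
#' @export
expected_cis <- function(matrix) {
  if (!inherits(matrix, "ContactMatrix")) stop_validation("not a ContactMatrix")
  if (!is_cis(matrix) || nrow(matrix$values) != ncol(matrix$values))
    stop_validation("expected_cis requires a square cis matrix")
  structure(list(chrom = matrix$chroms[1], values = .diag_means(matrix$values)),
            class = "ExpectedProfile")
}

#' Cis observed-over-expected matrix
#'
#' Divides each entry by the expected value at its offset. Entries are
#' missing where the observed value is missing, the expected value is
#' missing, or the expected value is exactly 0.
#'
#' @param matrix A cis [contact_matrix()].
#' @param expected An [expected_cis()] profile of matching dimension;
#'   computed from `matrix` when omitted.
#' @return A [contact_matrix()] of O/E values.
#' @export
oe_cis <- function(matrix, expected = expected_cis(matrix)) {
  if (!is_cis(matrix)) stop_validation("oe_cis requires a cis matrix")
  n <- nrow(matrix$values)
  if (length(expected$values) != n)
    stop_validation("expected profile length %d does not match matrix size %d",
                    length(expected$values), n)
  d <- abs(.row(dim(matrix$values)) - .col(dim(matrix$values)))
  e <- expected$values[d + 1L]
  e[!is.na(e) & e == 0] <- NA_real_
  out <- matrix
  out$values <- matrix$values / e
  out$values[!is.finite(out$values)] <- NA_real_
  out
}

#' Trans observed-over-expected matrix
#'
#' Divides every entry of a chromosome-pair matrix by the scalar mean of its
#' finite entries. An all-missing matrix (or a zero mean) maps to all-missing.
#'
#' @param matrix A trans [contact_matrix()].
#' @return A [contact_matrix()] of O/E values.
#' @export
oe_trans <- function(matrix) {
  if (!inherits(matrix, "ContactMatrix")) stop_validation("not a ContactMatrix")
  if (is_cis(matrix)) stop_validation("oe_trans requires a trans matrix")
  fin <- is.finite(matrix$values)
  out <- matrix
  if (!any(fin)) {
    out$values[] <- NA_real_
    return(out)
  }
  mu <- mean(matrix$values[fin])
  out$values <- if (mu == 0) matrix$values * NA_real_ else matrix$values / mu
  out$values[!is.finite(out$values)] <- NA_real_
  out
}

#' Observed-over-expected transform (cis or trans dispatch)
#'
#' @param matrix A [contact_matrix()].
#' @return The O/E matrix via [oe_cis()] or [oe_trans()].
#' @export
oe_transform <- function(matrix) {
  if (is_cis(matrix)) oe_cis(matrix) else oe_trans(matrix)
}
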