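# Area extraction, filtering, bilinear rescaling and median stacking into
# the pentad (the five-panel average compartment).

#' Pentad pipeline settings
#'
#' Collects the tunable parameters of the aggregation and strength steps.
#' The defaults are engineering choices (the underlying filters are part of
#' the method, their thresholds are not prescribed): `rescale_size` is odd so
#' a centre pixel exists.
#'
#' @param rescale_size Odd integer `S >= 3`; every area is rescaled to
#'   `S x S` pixels before averaging.
#' @param min_dimension Minimum area extent, in bins, on its smaller axis;
#'   smaller areas are dropped as noise.
#' @param max_zero_fraction Maximum tolerated fraction of missing-or-zero
#'   entries in an area (poor-coverage filter), in `[0, 1]`.
#' @param max_distance Optional anchor-distance cutoff in bp for cis areas
#'   (`NULL` = no cutoff); trans areas are never distance-filtered.
#' @param crop_fraction Fraction of the panel cropped from each side of the
#'   AB panel before the strength ratio, in `[0, 0.5)`.
#' @param distance_bins Increasing stratum boundaries in bp for the
#'   by-distance mode.
#' @param excluded_chroms Chromosome names to leave out of the analysis.
#' @return A `pentad_settings` list.
#' @export
pentad_settings <- function(rescale_size = 33L, min_dimension = 3L,
                            max_zero_fraction = 0.5, max_distance = NULL,
                            crop_fraction = 0.25,
                            distance_bins = c(10e6, 25e6, 50e6, 100e6),
                            excluded_chroms = character()) {
  .assert_scalar_num(rescale_size, "rescale_size", lo = 3)
  if (rescale_size %% 2 == 0)
    stop_validation("'rescale_size' must be odd (a centre pixel must exist)")
  .assert_scalar_num(min_dimension, "min_dimension", lo = 1)
  .assert_scalar_num(max_zero_fraction, "max_zero_fraction", lo = 0, hi = 1)
  if (!is.null(max_distance))
    .assert_scalar_num(max_distance, "max_distance", lo = 0)
  .assert_scalar_num(crop_fraction, "crop_fraction", lo = 0)
  if (crop_fraction >= 0.5)
    stop_validation("'crop_fraction' must be < 0.5")
  if (length(distance_bins) < 2L ||
      is.unsorted(distance_bins, strictly = TRUE))
    stop_validation("'distance_bins' must be >= 2 strictly increasing values")
  structure(list(rescale_size = as.integer(rescale_size),
                 min_dimension = as.integer(min_dimension),
                 max_zero_fraction = max_zero_fraction,
                 max_distance = max_distance,
                 crop_fraction = crop_fraction,
                 distance_bins = distance_bins,
                 excluded_chroms = excluded_chroms),
            class = "pentad_settings")
}

#' Extract one compartment area from an O/E matrix
#'
#' @param oe A [contact_matrix()] of O/E values.
#' @param area One-row data.frame of area descriptors
#'   (see [enumerate_areas_cis()]).
#' @return An `AreaMatrix`: the submatrix plus its descriptor.
#' @export
extract_area <- function(oe, area) {
  v <- oe$values
  if (area$row_start < 0 || area$col_start < 0 ||
      area$row_end > nrow(v) || area$col_end > ncol(v))
    stop_validation("area [%d,%d)x[%d,%d) outside the %dx%d matrix",
                    area$row_start, area$row_end, area$col_start,
                    area$col_end, nrow(v), ncol(v))
  structure(list(
    values = v[(area$row_start + 1L):area$row_end,
               (area$col_start + 1L):area$col_end, drop = FALSE],
    descriptor = area), class = "AreaMatrix")
}

#' Filter candidate areas
#'
#' Keeps an area iff (1) its smaller dimension is at least `min_dimension`
#' bins, (2) its fraction of missing-or-zero entries is at most
#' `max_zero_fraction`, and (3) its anchor distance does not exceed
#' `max_distance` (cis only; `NULL` disables the cutoff). Rejections are
#' attributed to the first failing rule in that order.
#'
#' @param areas List of [extract_area()] outputs.
#' @param min_dimension,max_zero_fraction,max_distance See
#'   [pentad_settings()].
#' @return List with `kept` (surviving `AreaMatrix` list) and `rejected`
#'   (named counts per rule: `dimension`, `contacts`, `distance`).
#' @export
filter_areas <- function(areas, min_dimension = 3L, max_zero_fraction = 0.5,
                         max_distance = NULL) {
  .assert_scalar_num(max_zero_fraction, "max_zero_fraction", lo = 0, hi = 1)
  rejected <- c(dimension = 0L, contacts = 0L, distance = 0L)
  keep <- logical(length(areas))
  for (k in seq_along(areas)) {
    a <- areas[[k]]
    v <- a$values
    if (min(dim(v)) < min_dimension) {
      rejected["dimension"] <- rejected["dimension"] + 1L
    } else if (mean(is.na(v) | (!is.na(v) & v == 0)) > max_zero_fraction) {
      rejected["contacts"] <- rejected["contacts"] + 1L
    } else if (!is.null(max_distance) &&
               identical(a$descriptor$context, "cis") &&
               !is.na(a$descriptor$distance) &&
               a$descriptor$distance > max_distance) {
      rejected["distance"] <- rejected["distance"] + 1L
    } else {
      keep[k] <- TRUE
    }
  }
  list(kept = areas[keep], rejected = rejected)
}

#' Rescale an area to a fixed square by bilinear interpolation
#'
#' Source sample centres sit at fractional positions of the unit square;
#' each target pixel interpolates its (up to) four nearest source samples.
#' A target pixel is missing iff any source sample contributing with
#' positive weight is missing — missingness propagates, values are never
#' imputed. A constant input yields the same constant at any size.
#'
#' @param area An `AreaMatrix` or a plain numeric matrix.
#' @param size Odd integer `S >= 3`.
#' @return `S x S` numeric matrix.
#' @export
rescale_area <- function(area, size = 33L) {
  v <- if (inherits(area, "AreaMatrix")) area$values else area
  if (!is.matrix(v)) stop_validation("'area' must be a matrix or AreaMatrix")
  .assert_scalar_num(size, "size", lo = 3)
  if (size %% 2 == 0) stop_validation("'size' must be odd")
  S <- as.integer(size)

  axis <- function(L) {
    pos <- (seq_len(S) - 0.5) / S * L - 0.5
    pos <- pmin(pmax(pos, 0), L - 1)
    i0 <- floor(pos)
    list(i0 = as.integer(i0) + 1L,
         i1 = pmin(as.integer(i0) + 2L, L),
         f = pos - i0)
  }
  ax <- axis(nrow(v))
  ay <- axis(ncol(v))

  gather <- function(ri, ci) v[ri, ci, drop = FALSE]
  m00 <- gather(ax$i0, ay$i0); m01 <- gather(ax$i0, ay$i1)
  m10 <- gather(ax$i1, ay$i0); m11 <- gather(ax$i1, ay$i1)
  w00 <- outer(1 - ax$f, 1 - ay$f); w01 <- outer(1 - ax$f, ay$f)
  w10 <- outer(ax$f, 1 - ay$f);     w11 <- outer(ax$f, ay$f)

  miss <- (w00 > 0 & is.na(m00)) | (w01 > 0 & is.na(m01)) |
          (w10 > 0 & is.na(m10)) | (w11 > 0 & is.na(m11))
  z <- function(m) { m[is.na(m)] <- 0; m }
  out <- w00 * z(m00) + w01 * z(m01) + w10 * z(m10) + w11 * z(m11)
  out[miss] <- NA_real_
  out
}

#' Median-average a stack of rescaled areas
#'
#' @param rescaled List of `S x S` matrices (all the same size).
#' @param size Panel size used when `rescaled` is empty (to shape the
#'   all-missing output).
#' @return List with `values` (`S x S` per-pixel median over non-missing
#'   contributors; missing iff missing in all) and `count`.
#' @export
stack_median <- function(rescaled, size = NULL) {
  if (!length(rescaled)) {
    if (is.null(size)) stop_validation("empty stack needs an explicit 'size'")
    return(list(values = matrix(NA_real_, size, size), count = 0L))
  }
  dims <- vapply(rescaled, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop_validation("all stacked arrays must share the same size")
  S1 <- dims[1, 1]; S2 <- dims[2, 1]
  arr <- array(unlist(rescaled, use.names = FALSE),
               dim = c(S1, S2, length(rescaled)))
  med <- apply(arr, c(1, 2), function(p) {
    p <- p[!is.na(p)]
    if (length(p)) stats::median(p) else NA_real_
  })
  list(values = med, count = length(rescaled))
}

# run enumerate -> extract -> filter -> rescale for one O/E map; returns
# list(areas = kept AreaMatrix list with $scaled, rejected = counts)
.process_map <- function(oe, areas_df, settings) {
  if (!nrow(areas_df))
    return(list(areas = list(),
                rejected = c(dimension = 0L, contacts = 0L, distance = 0L)))
  extracted <- lapply(seq_len(nrow(areas_df)), function(k)
    extract_area(oe, areas_df[k, , drop = FALSE]))
  flt <- filter_areas(extracted, settings$min_dimension,
                      settings$max_zero_fraction, settings$max_distance)
  flt$kept <- lapply(flt$kept, function(a) {
    a$scaled <- rescale_area(a, settings$rescale_size)
    a
  })
  list(areas = flt$kept, rejected = flt$rejected)
}

# panel key in distance mode
.panel_key <- function(type, stratum = NA_integer_) {
  ifelse(is.na(stratum), type, paste0(type, "@", stratum))
}

#' Build the pentad (average compartment)
#'
#' Orchestrates enumerate, extract, filter, rescale and median-stack over all
#' chromosomes (cis / by-distance) or chromosome pairs (trans), pooling
#' rescaled areas genome wide into one median stack per panel.
#'
#' @param oe_maps Named list of O/E [contact_matrix()] objects: per
#'   chromosome for `mode = "cis"`/`"distance"`, per pair (names
#'   `"chrA|chrB"`) for `mode = "trans"`.
#' @param intervals Named list of [segment_signal()] data.frames per
#'   chromosome.
#' @param mode `"cis"`, `"trans"` or `"distance"`.
#' @param settings A [pentad_settings()] object.
#' @param source Optional character description of the inputs, recorded in
#'   the provenance.
#' @return A `Pentad` object: named list of panels (each with `values`,
#'   `count`, `type`, `stratum` bounds), plus mode, size, settings,
#'   rejection counts.
#' @export
build_pentad <- function(oe_maps, intervals, mode = c("cis", "trans", "distance"),
                         settings = pentad_settings(), source = NULL) {
  mode <- match.arg(mode)
  S <- settings$rescale_size
  pools <- list()   # panel key -> list of rescaled matrices
  rejected <- c(dimension = 0L, contacts = 0L, distance = 0L)

  add <- function(key, mats) {
    if (!length(mats)) return()
    pools[[key]] <<- c(pools[[key]], mats)
  }

  if (mode %in% c("cis", "distance")) {
    for (ch in names(oe_maps)) {
      if (is.null(intervals[[ch]])) next
      areas_df <- enumerate_areas_cis(intervals[[ch]], oe_maps[[ch]]$binsize)
      got <- .process_map(oe_maps[[ch]], areas_df, settings)
      rejected <- rejected + got$rejected
      for (a in got$areas) {
        type <- a$descriptor$type
        if (mode == "distance" && type %in% c("A_long", "B_long", "AB")) {
          k <- assign_stratum(a$descriptor$distance, settings$distance_bins)
          if (is.na(k)) next  # outside all strata
          add(.panel_key(type, k), list(a$scaled))
        } else {
          add(type, list(a$scaled))
        }
      }
    }
  } else {
    for (pair in names(oe_maps)) {
      chs <- strsplit(pair, "|", fixed = TRUE)[[1]]
      if (length(chs) != 2L)
        stop_validation("trans map names must be 'chrA|chrB', got '%s'", pair)
      if (is.null(intervals[[chs[1]]]) || is.null(intervals[[chs[2]]])) next
      areas_df <- enumerate_areas_trans(intervals[[chs[1]]],
                                        intervals[[chs[2]]])
      got <- .process_map(oe_maps[[pair]], areas_df, settings)
      rejected <- rejected + got$rejected
      for (a in got$areas) add(a$descriptor$type, list(a$scaled))
    }
  }

  keys <- switch(mode,
    cis = AREA_TYPES,
    trans = c("A_long", "B_long", "AB"),
    distance = c("A_short", "B_short",
                 as.vector(t(outer(c("A_long", "B_long", "AB"),
                                   seq_len(length(settings$distance_bins) - 1L),
                                   .panel_key)))))
  panels <- list()
  for (key in keys) {
    stk <- stack_median(pools[[key]], size = S)
    if (stk$count == 0L)
      warning(sprintf("no areas survived filtering for panel '%s'", key),
              call. = FALSE)
    type <- sub("@.*$", "", key)
    strat <- if (grepl("@", key))
      as.integer(sub("^.*@", "", key)) else NA_integer_
    panels[[key]] <- list(
      values = stk$values, count = stk$count, type = type,
      stratum = strat,
      stratum_bp = if (!is.na(strat))
        settings$distance_bins[c(strat, strat + 1L)] else NULL)
  }

  structure(list(panels = panels, mode = mode, size = S,
                 settings = settings, rejected = rejected,
                 source = source),
            class = "Pentad")
}

#' @export
print.Pentad <- function(x, ...) {
  cat(sprintf("Pentad (%s mode, %dx%d panels)\n", x$mode, x$size, x$size))
  for (key in names(x$panels)) {
    p <- x$panels[[key]]
    med <- stats::median(p$values, na.rm = TRUE)
    cat(sprintf("  %-12s n=%4d  median O/E=%s\n", key, p$count,
                ifelse(is.na(med), "NA", sprintf("%.3f", med))))
  }
  cat(sprintf("  rejected: %d small, %d low-coverage, %d beyond cutoff\n",
              x$rejected["dimension"], x$rejected["contacts"],
              x$rejected["distance"]))
  invisible(x)
}

#' Write a pentad to JSON
#'
#' The JSON document is the interchange format between the compute, strength
#' and plot steps: per panel the full `S x S` grid (missing as `null`), the
#' contributing-area count and the stratum bounds, plus mode, size and all
#' settings.
#'
#' @param pentad A [build_pentad()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pentad <- function(pentad, path) {
  doc <- list(
    format = "pentad-json", version = 1L,
    mode = pentad$mode, size = pentad$size,
    settings = unclass(pentad$settings),
    rejected = as.list(pentad$rejected),
    source = pentad$source,
    panels = lapply(names(pentad$panels), function(key) {
      p <- pentad$panels[[key]]
      list(name = key, type = p$type,
           stratum = if (is.na(p$stratum)) NULL else p$stratum,
           stratum_bp = p$stratum_bp,
           count = p$count, values = p$values)
    }))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, na = "null",
                              digits = NA, null = "null"), path)
  invisible(path)
}

#' Read a pentad from JSON
#'
#' @param path Path written by [write_pentad()].
#' @return A `Pentad` object.
#' @export
read_pentad <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(doc$format, "pentad-json"))
    stop_validation("not a pentad JSON file: %s", path)
  panels <- list()
  for (p in doc$panels) {
    vals <- p$values
    if (is.list(vals))  # rows came back ragged (contain nulls)
      vals <- do.call(rbind, lapply(vals, function(r)
        vapply(r, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
               numeric(1))))
    storage.mode(vals) <- "double"
    panels[[p$name]] <- list(
      values = vals, count = p$count, type = p$type,
      stratum = if (is.null(p$stratum)) NA_integer_ else as.integer(p$stratum),
      stratum_bp = if (is.null(p$stratum_bp)) NULL else as.numeric(p$stratum_bp))
  }
  st <- doc$settings
  settings <- pentad_settings(
    rescale_size = st$rescale_size, min_dimension = st$min_dimension,
    max_zero_fraction = st$max_zero_fraction,
    max_distance = st$max_distance, crop_fraction = st$crop_fraction,
    distance_bins = as.numeric(st$distance_bins),
    excluded_chroms = as.character(unlist(st$excluded_chroms)))
  structure(list(panels = panels, mode = doc$mode, size = doc$size,
                 settings = settings,
                 rejected = unlist(doc$rejected), source = doc$source),
            class = "Pentad")
}
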