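# Extraction, filtering, bilinear rescaling, median stacking, build_pentad.

area_row <- function(rs, re, cs, ce, type = "A_long", dist = NA_real_,
                     context = "cis") {
  data.frame(chrom1 = "chr1", chrom2 = "chr1", row_start = rs, row_end = re,
             col_start = cs, col_end = ce, type = type, distance = dist,
             context = context, stringsAsFactors = FALSE)
}

test_that("extract_area slices the descriptor's block", {
  oe <- contact_matrix(matrix(1:100, 10, 10), "chr1", 1e5)
  a <- extract_area(oe, area_row(0, 2, 5, 8))
  expect_equal(a$values, oe$values[1:2, 6:8])

  sh <- extract_area(oe, area_row(3, 6, 3, 6, type = "A_short", dist = 0))
  expect_equal(dim(sh$values), c(3L, 3L))
  expect_equal(sh$values, oe$values[4:6, 4:6])

  expect_error(extract_area(oe, area_row(0, 2, 8, 11)),
               class = "pentad_validation_error")

  set.seed(20)
  oe40 <- random_cis_cm(40, seed = 20)
  for (k in 1:20) {
    rs <- sample(0:30, 1); re <- rs + sample(1:10, 1)
    cs <- sample(0:30, 1); ce <- cs + sample(1:10, 1)
    got <- extract_area(oe40, area_row(rs, re, cs, ce))$values
    ref <- matrix(NA_real_, re - rs, ce - cs)
    for (i in seq_len(re - rs)) for (j in seq_len(ce - cs))
      ref[i, j] <- oe40$values[rs + i, cs + j]
    expect_identical(got, ref)
  }
})

test_that("filter_areas applies its three rules in order", {
  mk <- function(nr, nc, zero_frac = 0, dist = NA_real_, context = "cis") {
    v <- matrix(1, nr, nc)
    nz <- round(zero_frac * nr * nc)
    if (nz > 0) v[seq_len(nz)] <- 0
    structure(list(values = v,
                   descriptor = area_row(0, nr, 0, nc, dist = dist,
                                         context = context)),
              class = "AreaMatrix")
  }
  f1 <- filter_areas(list(mk(2, 5)), min_dimension = 3)
  expect_length(f1$kept, 0)
  expect_equal(unname(f1$rejected["dimension"]), 1L)

  f2 <- filter_areas(list(mk(4, 4, zero_frac = 10 / 16)),
                     max_zero_fraction = 0.5)
  expect_equal(unname(f2$rejected["contacts"]), 1L)

  f3 <- filter_areas(list(mk(4, 4, dist = 2e6)), max_distance = 1e6)
  expect_equal(unname(f3$rejected["distance"]), 1L)
  # trans areas are never distance-filtered
  f4 <- filter_areas(list(mk(4, 4, context = "trans")), max_distance = 1)
  expect_length(f4$kept, 1)

  expect_error(filter_areas(list(), max_zero_fraction = 1.2),
               class = "pentad_validation_error")

  # randomized areas against the predicate-by-predicate oracle
  set.seed(31)
  areas <- lapply(1:100, function(k) {
    nr <- sample(1:8, 1); nc <- sample(1:8, 1)
    v <- matrix(runif(nr * nc), nr, nc)
    v[runif(nr * nc) < 0.2] <- 0
    v[runif(nr * nc) < 0.1] <- NA
    structure(list(values = v,
                   descriptor = area_row(0, nr, 0, nc,
                                         dist = runif(1, 0, 5e6))),
              class = "AreaMatrix")
  })
  got <- filter_areas(areas, min_dimension = 3, max_zero_fraction = 0.4,
                      max_distance = 3e6)
  want <- vapply(areas, function(a)
    oracle_filter_keep(a$values, a$descriptor$distance, "cis", 3, 0.4, 3e6),
    logical(1))
  expect_length(got$kept, sum(want))
  expect_equal(sum(got$rejected), sum(!want))

  # monotone filtering: stricter settings never keep more
  for (md in 1:5) {
    k1 <- length(filter_areas(areas, min_dimension = md)$kept)
    k2 <- length(filter_areas(areas, min_dimension = md + 1)$kept)
    expect_lte(k2, k1)
  }
  for (zf in c(0.8, 0.5, 0.2)) {
    k1 <- length(filter_areas(areas, max_zero_fraction = zf)$kept)
    k2 <- length(filter_areas(areas, max_zero_fraction = zf - 0.1)$kept)
    expect_lte(k2, k1)
  }
})

test_that("bilinear rescaling preserves constants and matches the oracle", {
  for (S in c(3, 11, 33))
    expect_equal(rescale_area(matrix(2, 3, 3), S), matrix(2, S, S))

  out <- rescale_area(matrix(c(0, 1, 1, 0), 2, 2), 3)
  expect_equal(out[2, 2], 0.5)

  set.seed(40)
  v <- matrix(runif(35, 0.2, 4), 5, 7)
  expect_equal(rescale_area(v, 33), oracle_bilinear(v, 33),
               tolerance = 1e-9)

  # missingness propagates to every pixel the NA sample contributes to
  vna <- v; vna[3, 4] <- NA
  got <- rescale_area(vna, 33)
  ref <- oracle_bilinear(vna, 33)
  expect_identical(is.na(got), is.na(ref))
  expect_equal(got, ref, tolerance = 1e-9)
  expect_true(any(is.na(got)) && !all(is.na(got)))

  expect_error(rescale_area(v, 32), class = "pentad_validation_error")
  expect_error(rescale_area(v, 1), class = "pentad_validation_error")
})

test_that("stack_median is a per-pixel NA-aware median", {
  m <- matrix(runif(9), 3, 3)
  expect_equal(stack_median(list(m, m, m))$values, m)

  trio <- list(matrix(1, 2, 2), matrix(2, 2, 2), matrix(100, 2, 2))
  expect_equal(stack_median(trio)$values, matrix(2, 2, 2))
  expect_equal(stack_median(trio)$count, 3L)

  set.seed(50)
  mats <- lapply(1:25, function(k) {
    x <- matrix(runif(121, 0, 3), 11, 11)
    x[runif(121) < 0.15] <- NA
    x
  })
  got <- stack_median(mats)
  expect_equal(got$values, oracle_median_stack(mats))
  # permutation invariance
  expect_equal(stack_median(rev(mats))$values, got$values)

  expect_error(stack_median(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               class = "pentad_validation_error")
  empty <- stack_median(list(), size = 5)
  expect_true(all(is.na(empty$values)) && empty$count == 0)
})

test_that("build_pentad pools the expected area counts", {
  st <- pentad_settings(rescale_size = 11, min_dimension = 3)
  g <- mini_genome(f = 2, nbins_half = 10, chroms = 2)
  oe <- synthetic_oe(g, "true")

  p <- suppressWarnings(build_pentad(oe$cis, g$intervals, "cis", st))
  counts <- vapply(p$panels, `[[`, integer(1), "count")
  expect_equal(counts, c(A_short = 2L, B_short = 2L, A_long = 0L,
                         B_long = 0L, AB = 2L))

  pt <- build_pentad(oe$trans, g$intervals, "trans", st)
  expect_equal(vapply(pt$panels, `[[`, integer(1), "count"),
               c(A_long = 1L, B_long = 1L, AB = 2L))

  # the planted O/E is constant per type, so panels are exact constants
  expect_equal(p$panels$A_short$values, matrix(2, 11, 11))
  expect_equal(p$panels$AB$values, matrix(0.5, 11, 11))
  expect_equal(pt$panels$B_long$values, matrix(2, 11, 11))
})

test_that("pentad panels are homogeneous of degree one in O/E", {
  g <- mini_genome(f = 2, nbins_half = 6, chroms = 2, seed = 13)
  oe <- synthetic_oe(g, "true")
  st <- pentad_settings(rescale_size = 11, min_dimension = 3)
  p1 <- suppressWarnings(build_pentad(oe$cis, g$intervals, "cis", st))
  oe_scaled <- lapply(oe$cis, function(cm) {
    cm$values <- cm$values * 3.7
    cm
  })
  p2 <- suppressWarnings(build_pentad(oe_scaled, g$intervals, "cis", st))
  for (key in names(p1$panels))
    expect_equal(p2$panels[[key]]$values, 3.7 * p1$panels[[key]]$values,
                 tolerance = 1e-12)
})

test_that("pentad JSON round-trips values, counts and settings", {
  g <- mini_genome(f = 1.5, nbins_half = 5, chroms = 2, seed = 3,
                   noise = "poisson")
  oe <- synthetic_oe(g, "empirical")
  st <- pentad_settings(rescale_size = 11, max_distance = 4e6,
                        distance_bins = c(0, 2e6, 4e6))
  p <- suppressWarnings(build_pentad(oe$cis, g$intervals, "distance", st))
  f <- tempfile(fileext = ".json")
  write_pentad(p, f)
  q <- read_pentad(f)
  expect_equal(q$mode, "distance")
  expect_equal(q$size, 11L)
  expect_equal(names(q$panels), names(p$panels))
  for (key in names(p$panels)) {
    expect_equal(q$panels[[key]]$values, p$panels[[key]]$values)
    expect_equal(q$panels[[key]]$count, p$panels[[key]]$count)
  }
  expect_equal(q$settings$max_distance, 4e6)
  expect_equal(q$settings$distance_bins, c(0, 2e6, 4e6))
})
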