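# Compartment strength and condition comparison.

test_that("crop_center removes floor(crop * S) pixels per side", {
  p33 <- matrix(seq_len(33 * 33), 33, 33)
  out <- crop_center(p33, 0.25)
  expect_equal(dim(out), c(17L, 17L))
  expect_identical(out, p33[9:25, 9:25])
  expect_identical(crop_center(p33, 0), p33)

  set.seed(61)
  p <- matrix(runif(33 * 33), 33, 33)
  k <- floor(0.25 * 33)
  expect_identical(crop_center(p, 0.25), p[(k + 1):(33 - k), (k + 1):(33 - k)])

  expect_error(crop_center(p33, 0.5), class = "pentad_validation_error")
  # crop < 0.5 always leaves >= 1 pixel, even on a 1 x 1 panel
  expect_identical(crop_center(matrix(1, 1, 1), 0.45), matrix(1, 1, 1))
})

test_that("strength is the within/cropped-between mean ratio", {
  mk <- function(x) matrix(x, 11, 11)
  panels <- list(A_short = mk(2), B_short = mk(2), A_long = mk(2),
                 B_long = mk(2), AB = mk(0.5))
  s <- compartment_strength(panels, 0.25)
  expect_equal(unname(s), rep(4, 5))

  ones <- lapply(panels, function(p) mk(1))
  expect_equal(unname(compartment_strength(ones, 0.25)), rep(1, 5))

  # missing numerator panel -> NA for that type only
  p2 <- panels; p2$B_long <- mk(NA_real_)
  s2 <- compartment_strength(p2, 0.25)
  expect_true(is.na(s2["B_long"]))
  expect_equal(unname(s2["A_short"]), 4)

  expect_error(compartment_strength(panels[c("A_short", "B_short")], 0.25),
               class = "pentad_validation_error")  # no AB panel
})

test_that("noise-free planted contrast recovers f^2 exactly", {
  for (f in c(1.5, 2)) {
    g <- mini_genome(f = f, nbins_half = 10, chroms = 1)
    oe <- synthetic_oe(g, "true")
    p <- suppressWarnings(build_pentad(oe$cis, g$intervals, "cis",
                                       pentad_settings(rescale_size = 11)))
    s <- compartment_strength(p, 0.25)
    # brute-force mean-ratio oracle straight from the planted block matrix
    lab <- g$labels$chr1
    same <- outer(lab, lab, `==`)
    v <- oe$cis$chr1$values
    oracle <- mean(v[same]) / mean(v[!same])
    expect_equal(unname(s["combined"]), f^2, tolerance = 1e-6)
    expect_equal(unname(s["combined"]), oracle, tolerance = 1e-6)
  }
})

test_that("strength_genome yields one row per chromosome", {
  g <- mini_genome(f = 2, nbins_half = 8, chroms = 2)
  oe <- synthetic_oe(g, "true")
  tab <- strength_genome(oe$cis, g$intervals,
                         pentad_settings(rescale_size = 11))
  expect_s3_class(tab, "StrengthTable")
  expect_equal(tab$chrom, c("chr1", "chr2"))
  expect_equal(names(tab), c("chrom", "A_short", "B_short", "A_long",
                             "B_long", "combined"))
  expect_equal(tab$combined, c(4, 4), tolerance = 1e-6)
  # no long-range areas exist in a one-A-one-B layout
  expect_true(all(is.na(tab$A_long)))

  # a chromosome without B intervals has no B (nor AB) strengths
  iv_a_only <- data.frame(chrom = "chr2", start = 0, end = 16, label = "A",
                          mean_signal = 1)
  tab2 <- strength_genome(oe$cis, list(chr1 = g$intervals$chr1,
                                       chr2 = iv_a_only),
                          pentad_settings(rescale_size = 11))
  r2 <- tab2[tab2$chrom == "chr2", ]
  expect_true(is.na(r2$B_short) && is.na(r2$B_long))

  # TSV round trip
  f <- tempfile(fileext = ".tsv")
  write_strength_table(tab, f)
  back <- read_strength_table(f)
  expect_equal(back$combined, tab$combined)
  expect_equal(back$chrom, tab$chrom)
})

test_that("strength is invariant to global O/E rescaling", {
  g <- mini_genome(f = 2, nbins_half = 8, chroms = 1, seed = 9)
  oe <- synthetic_oe(g, "true")$cis
  st <- pentad_settings(rescale_size = 11)
  t1 <- strength_genome(oe, g$intervals, st)
  oe_scaled <- lapply(oe, function(cm) { cm$values <- cm$values * 5.5; cm })
  t2 <- strength_genome(oe_scaled, g$intervals, st)
  expect_equal(t2$combined, t1$combined, tolerance = 1e-12)
  expect_equal(t2$A_short, t1$A_short, tolerance = 1e-12)
})

test_that("combined strength increases with planted contrast", {
  vals <- vapply(c(1, 1.5, 2, 3), function(f) {
    g <- mini_genome(f = f, nbins_half = 6, chroms = 1, seed = 2)
    oe <- synthetic_oe(g, "true")
    tab <- strength_genome(oe$cis, g$intervals,
                           pentad_settings(rescale_size = 11))
    tab$combined[1]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(vals, c(1, 1.5, 2, 3)^2, tolerance = 1e-6)
})

mk_table <- function(chroms, values) {
  tab <- data.frame(chrom = chroms, A_short = values, B_short = values,
                    A_long = values, B_long = values, combined = values)
  structure(tab, class = c("StrengthTable", "data.frame"))
}

test_that("compare_conditions implements the paired signed-rank test", {
  set.seed(77)
  x <- runif(10, 1, 3)
  t1 <- mk_table(paste0("chr", 1:10), x)

  # self comparison: all differences zero -> p = 1
  self <- compare_conditions(t1, t1)
  expect_true(all(self$p_value == 1))
  expect_true(all(self$significance == "ns"))

  # uniform +0.5 shift: one-sided extreme, exact two-sided p = 2/2^10
  t2 <- mk_table(paste0("chr", 1:10), x + 0.5)
  cmp <- compare_conditions(t1, t2)
  expect_equal(cmp$p_value, rep(2 / 2^10, 5), tolerance = 1e-12)
  expect_equal(cmp$statistic, rep(0, 5))
  expect_equal(cmp$significance, rep("**", 5))

  # random paired samples vs the exact-enumeration oracle
  for (seed in c(21, 22)) {
    set.seed(seed)
    a <- runif(12, 1, 4); b <- a + rnorm(12, 0, 0.4)
    ta <- mk_table(paste0("chr", 1:12), a)
    tb <- mk_table(paste0("chr", 1:12), b)
    got <- compare_conditions(ta, tb)
    ora <- oracle_signrank(a - b)
    expect_equal(got$statistic, rep(ora$W, 5))
    expect_equal(got$p_value, rep(ora$p, 5), tolerance = 1e-12)
    # cross-implementation check against the reference exact test (no ties)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(got$statistic[1], unname(ref$statistic))
    expect_equal(got$p_value[1], ref$p.value, tolerance = 1e-12)
  }

  # two-sided p is symmetric under swapping the conditions
  swapped <- compare_conditions(t2, t1)
  expect_equal(swapped$p_value, cmp$p_value, tolerance = 1e-12)

  expect_error(compare_conditions(t1, mk_table(paste0("x", 1:10), x)),
               class = "pentad_validation_error")
  ws <- capture_warnings(compare_conditions(
    mk_table(paste0("chr", 1:3), 1:3),
    mk_table(paste0("chr", 1:3), c(2, 1, 4))))
  expect_true(all(grepl("finite pairs", ws)) && length(ws) == 5)
})
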