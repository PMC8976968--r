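# CLI orchestration and figure rendering.

cli_tmp <- function(...) file.path(tempdir(), paste0(...))

test_that("simulate -> cis -> strength smoke path succeeds end to end", {
  pre <- cli_tmp("smoke")
  expect_equal(run_command(c("simulate", "--seed", "7", "--n-chroms", "2",
                             "--chrom-length", "6000000",
                             "--out-prefix", pre)), 0L)
  expect_true(file.exists(paste0(pre, ".cool")))

  out <- cli_tmp("smoke_cis")
  expect_equal(run_command(c("cis", paste0(pre, ".cool"),
                             paste0(pre, ".bedGraph"),
                             "--rescale-size", "11",
                             "--out-prefix", out)), 0L)
  p <- read_pentad(paste0(out, ".pentad.json"))
  expect_s3_class(p, "Pentad")
  expect_equal(p$size, 11L)
  expect_named(p$panels, c("A_short", "B_short", "A_long", "B_long", "AB"))

  sout <- cli_tmp("smoke_str")
  expect_equal(run_command(c("strength", paste0(pre, ".cool"),
                             paste0(pre, ".bedGraph"),
                             "--rescale-size", "11",
                             "--out-prefix", sout)), 0L)
  tab <- read_strength_table(paste0(sout, ".strength.tsv"))
  expect_equal(nrow(tab), 2)

  cfg <- jsonlite::read_json(paste0(out, ".config.json"))
  expect_equal(cfg$mode, "cis")
  expect_equal(cfg$settings$rescale_size, 11)
})

test_that("CLI reports user errors with status 1, not a stack trace", {
  expect_equal(suppressMessages(run_command(character())), 1L)
  expect_equal(suppressMessages(run_command(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(
    run_command(c("cis", "no_such.cool", "no_such.bedGraph"))), 1L)
  msg <- capture.output(
    st <- run_command(c("cis", "a.cool", "b.bedGraph", "--bogus", "1")),
    type = "message")
  expect_equal(st, 1L)
  expect_match(paste(msg, collapse = " "), "--bogus")
})

test_that("bin-size mismatch diagnostic names both sizes", {
  pre <- cli_tmp("mm100")
  run_command(c("simulate", "--seed", "3", "--n-chroms", "1",
                "--chrom-length", "4000000", "--out-prefix", pre))
  pre50 <- cli_tmp("mm50")
  run_command(c("simulate", "--seed", "3", "--n-chroms", "1",
                "--chrom-length", "4000000", "--bin-size", "50000",
                "--out-prefix", pre50))
  msg <- capture.output(
    st <- run_command(c("cis", paste0(pre, ".cool"),
                        paste0(pre50, ".bedGraph"),
                        "--out-prefix", cli_tmp("mm_out"))),
    type = "message")
  expect_equal(st, 1L)
  expect_match(paste(msg, collapse = " "), "100000")
  expect_match(paste(msg, collapse = " "), "50000")
})

test_that("identical run configuration reproduces outputs bit for bit", {
  pre <- cli_tmp("rep")
  run_command(c("simulate", "--seed", "5", "--n-chroms", "2",
                "--chrom-length", "5000000", "--out-prefix", pre))
  args <- c("cis", paste0(pre, ".cool"), paste0(pre, ".bedGraph"),
            "--rescale-size", "11")
  o1 <- cli_tmp("rep_a"); o2 <- cli_tmp("rep_b")
  expect_equal(run_command(c(args, "--out-prefix", o1)), 0L)
  expect_equal(run_command(c(args, "--out-prefix", o2)), 0L)
  expect_identical(readLines(paste0(o1, ".pentad.json")),
                   readLines(paste0(o2, ".pentad.json")))
  # simulate twice with one seed: identical fixture content
  pre2 <- cli_tmp("rep2")
  run_command(c("simulate", "--seed", "5", "--n-chroms", "2",
                "--chrom-length", "5000000", "--out-prefix", pre2))
  expect_identical(readLines(paste0(pre, ".bedGraph")),
                   readLines(paste0(pre2, ".bedGraph")))
  m1 <- read_contact_matrix(paste0(pre, ".cool"), "chr1")
  m2 <- read_contact_matrix(paste0(pre2, ".cool"), "chr1")
  expect_identical(m1$values, m2$values)
})

mk_const_pentad <- function(vals, S = 11) {
  panels <- lapply(names(vals), function(k)
    list(values = matrix(vals[[k]], S, S), count = 3L,
         type = k, stratum = NA_integer_, stratum_bp = NULL))
  names(panels) <- names(vals)
  structure(list(panels = panels, mode = "cis", size = S,
                 settings = pentad_settings(rescale_size = S),
                 rejected = c(dimension = 0L, contacts = 0L, distance = 0L),
                 source = NULL), class = "Pentad")
}

test_that("render_pentad draws the five-slot composite", {
  p <- mk_const_pentad(list(A_short = 1, B_short = 1, A_long = 1,
                            B_long = 1, AB = 1))
  f <- tempfile(fileext = ".png")
  res <- render_pentad(p, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_equal(dim(res$layout), c(3L, 3L))
  expect_equal(res$layout[1, 1], "A_short")
  expect_equal(res$layout[2, 2], "AB")
  expect_equal(res$layout[3, 3], "B_short")
  expect_equal(res$layout[1, 3], "A_long")
  expect_equal(res$layout[3, 1], "B_long")
  # all-ones pentad: every drawn grid sits at the colour-scale midpoint
  expect_true(all(vapply(res$panels, function(q) all(q$values == 1),
                         logical(1))))

  p2 <- mk_const_pentad(list(A_short = 2, B_short = 2, A_long = 2,
                             B_long = 2, AB = 0.5))
  res2 <- render_pentad(p2, tempfile(fileext = ".pdf"))
  expect_equal(res2$panels$A_short$values[1, 1], 2)
  expect_equal(res2$panels$AB$values[1, 1], 0.5)

  # all-missing pentad renders (as "no data"), nonfatally
  pna <- mk_const_pentad(list(A_short = NA_real_, B_short = NA_real_,
                              A_long = NA_real_, B_long = NA_real_,
                              AB = NA_real_))
  fna <- tempfile(fileext = ".png")
  expect_no_error(render_pentad(pna, fna))
  expect_true(file.exists(fna))

  expect_error(render_pentad(p, tempfile(fileext = ".bmp")),
               class = "pentad_validation_error")
  expect_error(render_pentad(p, zlim = c(2, 1)),
               class = "pentad_validation_error")
})

test_that("distance-mode figures have one column per stratum", {
  g <- mini_genome(f = 2, nbins_half = 10, chroms = 2)
  oe <- synthetic_oe(g, "true")
  st <- pentad_settings(rescale_size = 11,
                        distance_bins = c(0, 1e6, 2e6, 4e6))
  p <- suppressWarnings(build_pentad(oe$cis, g$intervals, "distance", st))
  res <- render_pentad(p, tempfile(fileext = ".png"))
  expect_equal(ncol(res$layout), 1 + 3)  # short panels + 3 strata
  expect_equal(res$layout[, 1], c("A_short", "", "B_short"))
  expect_equal(res$layout[2, 2:4], paste0("AB@", 1:3))
})
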