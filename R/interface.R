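# Command-line entry point and figure rendering. The CLI is pure
# orchestration: every number it writes is the output of a module function
# on the same inputs, and the full run configuration is recorded next to
# every output for bit-for-bit reproducibility.

# --key value / --key=value parser; boolean flags listed in 'switches'
.parse_flags <- function(argv, switches = character()) {
  flags <- list(); pos <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        flags[[kv[1]]] <- paste(kv[-1], collapse = "=")
      } else if (key %in% switches) {
        flags[[key]] <- TRUE
      } else {
        if (i == length(argv))
          stop_validation("flag --%s needs a value", key)
        flags[[key]] <- argv[i + 1L]
        i <- i + 1L
      }
    } else {
      pos <- c(pos, a)
    }
    i <- i + 1L
  }
  list(flags = flags, positional = pos)
}

.flag_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) return(default)
  v <- suppressWarnings(as.numeric(flags[[key]]))
  if (is.na(v)) stop_validation("flag --%s: '%s' is not a number",
                                key, flags[[key]])
  v
}

.flag_chr <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) default else flags[[key]]
}

.settings_from_flags <- function(flags) {
  db <- .flag_chr(flags, "distance-bins")
  pentad_settings(
    rescale_size = .flag_num(flags, "rescale-size", 33),
    min_dimension = .flag_num(flags, "min-dimension", 3),
    max_zero_fraction = .flag_num(flags, "max-zeros", 0.5),
    max_distance = .flag_num(flags, "cutoff", NULL),
    crop_fraction = .flag_num(flags, "crop", 0.25),
    distance_bins = if (is.null(db)) c(10e6, 25e6, 50e6, 100e6)
                    else as.numeric(strsplit(db, ",")[[1]]),
    excluded_chroms = if (is.null(flags[["exclude-chroms"]])) character()
                      else strsplit(flags[["exclude-chroms"]], ",")[[1]])
}

.known_flags <- c("resolution", "rescale-size", "min-dimension", "max-zeros",
                  "cutoff", "crop", "distance-bins", "exclude-chroms",
                  "no-balance", "seed", "out-prefix", "format",
                  "n-chroms", "chrom-length", "bin-size", "f", "alpha",
                  "noise", "depth", "depth-trans", "missing")

# load cooler + bedGraph, validate, return O/E-ready pieces
.load_inputs <- function(cool, bedgraph, flags, settings) {
  resolution <- .flag_num(flags, "resolution", NULL)
  bins <- cooler_genome_bins(cool, resolution)
  tracks <- read_compartment_signal(bedgraph, bins)
  report <- validate_inputs(bins, tracks)
  shared <- setdiff(report$shared_chroms, settings$excluded_chroms)
  if (!length(shared))
    stop_validation("all shared chromosomes were excluded")
  balanced <- if (isTRUE(flags[["no-balance"]])) FALSE else NA
  list(bins = bins, tracks = tracks, shared = shared,
       resolution = resolution, balanced = balanced)
}

.write_config <- function(prefix, mode, flags, settings, inputs = NULL) {
  cfg <- list(mode = mode, inputs = inputs,
              flags = flags, settings = unclass(settings),
              version = as.character(utils::packageVersion("hicpentad")))
  jsonlite::write_json(cfg, paste0(prefix, ".config.json"),
                       auto_unbox = TRUE, na = "null", digits = NA)
}

.cli_oe_cis_maps <- function(inp, cool, flags) {
  maps <- list()
  for (ch in inp$shared) {
    cm <- read_contact_matrix(cool, ch, use_balanced = inp$balanced,
                              resolution = inp$resolution)
    maps[[ch]] <- oe_cis(cm)
  }
  maps
}

#' Run the command-line interface
#'
#' Subcommands: `cis`, `trans`, `distance` (pentad JSON from a cooler + a
#' bedGraph, plus an optional figure when `--format` is given); `strength`
#' (per-chromosome TSV); `compare` (Wilcoxon report TSV from two strength
#' tables); `plot` (figure from a pentad JSON); `simulate` (synthetic
#' fixture files). Common flags: `--resolution`, `--rescale-size`,
#' `--min-dimension`, `--max-zeros`, `--cutoff`, `--crop`,
#' `--distance-bins`, `--exclude-chroms`, `--no-balance`, `--seed`,
#' `--out-prefix`, `--format`.
#'
#' Invoke from a shell as
#' `Rscript -e 'quit(status = hicpentad::run_command(commandArgs(TRUE)))' -- ...`
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Exit status, invisibly: 0 on success, 1 on a user/validation
#'   error (with a one-line diagnostic on stderr).
#' @export
run_command <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    .dispatch_command(argv)
    0L
  }, pentad_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  }, error = function(e) {
    message("internal error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.dispatch_command <- function(argv) {
  if (!length(argv))
    stop_validation(paste("no command given; available:",
                          "cis trans distance strength compare plot simulate"))
  cmd <- argv[1]
  parsed <- .parse_flags(argv[-1], switches = "no-balance")
  flags <- parsed$flags
  unknown <- setdiff(names(flags), .known_flags)
  if (length(unknown))
    stop_validation("unknown flag(s): %s",
                    paste0("--", unknown, collapse = ", "))
  pos <- parsed$positional
  prefix <- .flag_chr(flags, "out-prefix", "pentad_out")
  settings <- .settings_from_flags(flags)
  fmt <- .flag_chr(flags, "format")

  need_inputs <- function(n, what) {
    if (length(pos) != n)
      stop_validation("'%s' needs %d input file(s): %s", cmd, n, what)
  }

  if (cmd %in% c("cis", "distance")) {
    need_inputs(2L, "<matrix.cool> <signal.bedGraph>")
    inp <- .load_inputs(pos[1], pos[2], flags, settings)
    maps <- .cli_oe_cis_maps(inp, pos[1], flags)
    ivs <- lapply(inp$tracks[inp$shared], segment_signal)
    p <- build_pentad(maps, ivs, mode = cmd, settings = settings,
                      source = paste(pos, collapse = " "))
    write_pentad(p, paste0(prefix, ".pentad.json"))
    .write_config(prefix, cmd, flags, settings, inputs = pos)
    if (!is.null(fmt))
      render_pentad(p, paste0(prefix, ".", fmt))
  } else if (cmd == "trans") {
    need_inputs(2L, "<matrix.cool> <signal.bedGraph>")
    inp <- .load_inputs(pos[1], pos[2], flags, settings)
    if (length(inp$shared) < 2L)
      stop_validation("trans mode needs at least two shared chromosomes")
    maps <- list()
    for (i in seq_len(length(inp$shared) - 1L))
      for (j in (i + 1L):length(inp$shared)) {
        pair <- inp$shared[c(i, j)]
        cm <- read_contact_matrix(pos[1], pair, use_balanced = inp$balanced,
                                  resolution = inp$resolution)
        maps[[paste(pair, collapse = "|")]] <- oe_trans(cm)
      }
    ivs <- lapply(inp$tracks[inp$shared], segment_signal)
    p <- build_pentad(maps, ivs, mode = "trans", settings = settings,
                      source = paste(pos, collapse = " "))
    write_pentad(p, paste0(prefix, ".pentad.json"))
    .write_config(prefix, cmd, flags, settings, inputs = pos)
    if (!is.null(fmt))
      render_pentad(p, paste0(prefix, ".", fmt))
  } else if (cmd == "strength") {
    need_inputs(2L, "<matrix.cool> <signal.bedGraph>")
    inp <- .load_inputs(pos[1], pos[2], flags, settings)
    maps <- .cli_oe_cis_maps(inp, pos[1], flags)
    ivs <- lapply(inp$tracks[inp$shared], segment_signal)
    tab <- strength_genome(maps, ivs, settings)
    write_strength_table(tab, paste0(prefix, ".strength.tsv"))
    .write_config(prefix, cmd, flags, settings, inputs = pos)
  } else if (cmd == "compare") {
    need_inputs(2L, "<strength1.tsv> <strength2.tsv>")
    rep <- compare_conditions(read_strength_table(pos[1]),
                              read_strength_table(pos[2]))
    write_comparison(rep, paste0(prefix, ".compare.tsv"))
    .write_config(prefix, cmd, flags, settings, inputs = pos)
  } else if (cmd == "plot") {
    need_inputs(1L, "<pentad.json>")
    p <- read_pentad(pos[1])
    render_pentad(p, paste0(prefix, ".", if (is.null(fmt)) "png" else fmt))
    .write_config(prefix, cmd, flags, settings, inputs = pos)
  } else if (cmd == "simulate") {
    need_inputs(0L, "")
    nchr <- .flag_num(flags, "n-chroms", 4)
    chrlen <- .flag_num(flags, "chrom-length", 50e6)
    spec <- synthetic_spec(
      chroms = setNames(rep(chrlen, nchr), paste0("chr", seq_len(nchr))),
      binsize = .flag_num(flags, "bin-size", 100e3),
      f = .flag_num(flags, "f", 2),
      alpha = .flag_num(flags, "alpha", 1),
      noise = .flag_chr(flags, "noise", "poisson"),
      depth = .flag_num(flags, "depth", 1000),
      depth_trans = .flag_num(flags, "depth-trans", 10),
      missing_fraction = .flag_num(flags, "missing", 0.02),
      seed = .flag_num(flags, "seed", 1))
    files <- write_fixture(generate_genome(spec), prefix)
    .write_config(prefix, cmd, flags,
                  .settings_from_flags(flags), inputs = unname(files))
  } else {
    stop_validation("unknown command '%s'", cmd)
  }
  invisible(NULL)
}

# panel slot layout of the composite figure; "" = empty slot
.pentad_layout <- function(pentad) {
  if (pentad$mode == "cis") {
    matrix(c("A_short", "",   "A_long",
             "",        "AB", "",
             "B_long",  "",   "B_short"), 3, 3, byrow = TRUE)
  } else if (pentad$mode == "trans") {
    matrix(c("A_long", "",   "",
             "",       "AB", "",
             "",       "",   "B_long"), 3, 3, byrow = TRUE)
  } else {
    nstrat <- length(pentad$settings$distance_bins) - 1L
    cols <- c(list(c("A_short", "", "B_short")),
              lapply(seq_len(nstrat), function(k)
                paste0(c("A_long", "AB", "B_long"), "@", k)))
    do.call(cbind, cols)
  }
}

#' Render a pentad figure
#'
#' Draws the composite average-compartment figure: short-range A and B
#' squares flanking the central A-B square on the diagonal, long-range A/B
#' squares in the off-diagonal corners (by-distance mode: one column of
#' long-range/AB panels per stratum, labelled with its bp range, next to
#' the unstratified short-range panels). O/E values are shown on a log
#' scale with a diverging palette centred at 1; per-panel contributing-area
#' counts are annotated. All-missing panels render as "no data".
#'
#' @param pentad A [build_pentad()] or [read_pentad()] result.
#' @param file Output figure path (`.png`, `.pdf` or `.svg`); `NULL` draws
#'   on the current device.
#' @param zlim Colour limits on the O/E scale, symmetric in log space.
#' @param palette Colour vector for the diverging scale.
#' @return Invisibly, the slot layout matrix and the panel list actually
#'   drawn (for programmatic checks).
#' @export
render_pentad <- function(pentad, file = NULL, zlim = c(0.5, 2),
                          palette = colorRampPalette(
                            c("#2166AC", "#F7F7F7", "#B2182B"))(255)) {
  if (!inherits(pentad, "Pentad")) stop_validation("not a Pentad")
  if (length(zlim) != 2 || any(zlim <= 0) || zlim[1] >= zlim[2])
    stop_validation("'zlim' must be two increasing positive values")
  slots <- .pentad_layout(pentad)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    w <- 2.2 * ncol(slots); h <- 2.2 * nrow(slots) + 0.4
    switch(ext,
           png = grDevices::png(file, width = w, height = h, units = "in",
                                res = 150),
           pdf = grDevices::pdf(file, width = w, height = h),
           svg = grDevices::svg(file, width = w, height = h),
           stop_validation("unsupported figure format '%s'", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = dim(slots), mar = c(0.6, 0.6, 1.6, 0.6),
                      oma = c(0, 0, 1.2, 0))
  on.exit(graphics::par(op), add = TRUE)

  lz <- log2(zlim)
  drawn <- list()
  for (r in seq_len(nrow(slots))) for (cc in seq_len(ncol(slots))) {
    key <- slots[r, cc]
    if (key == "" || is.null(pentad$panels[[key]])) {
      graphics::plot.new()
      next
    }
    p <- pentad$panels[[key]]
    lab <- if (!is.null(p$stratum_bp))
      sprintf("%s %s-%s Mb", p$type, p$stratum_bp[1] / 1e6,
              p$stratum_bp[2] / 1e6) else p$type
    if (all(is.na(p$values))) {
      graphics::plot.new()
      graphics::text(0.5, 0.5, "no data", cex = 1.1, col = "grey40")
      graphics::title(main = lab, cex.main = 0.9)
    } else {
      z <- log2(p$values)
      z[!is.finite(z)] <- NA
      z <- pmin(pmax(z, lz[1]), lz[2])
      # image() draws rows as x: transpose and flip so row 1 is on top
      graphics::image(t(z[nrow(z):1, , drop = FALSE]), axes = FALSE,
                      zlim = lz, col = palette, useRaster = FALSE)
      graphics::box(col = "grey60")
      graphics::title(main = lab, cex.main = 0.9)
      graphics::mtext(sprintf("n=%d", p$count), side = 1, line = -1.1,
                      adj = 0.98, cex = 0.6)
    }
    drawn[[key]] <- p
  }
  graphics::mtext(sprintf("average compartment (%s), O/E in [%g, %g]",
                          pentad$mode, zlim[1], zlim[2]),
                  outer = TRUE, cex = 0.8)
  invisible(list(layout = slots, panels = drawn, zlim = zlim))
}
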