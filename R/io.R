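# Readers/writers and the end-to-end pipeline. All tabular interchange is
# plain TSV; intervals are BED (0-based half-open, no header).

COUNTS_COLUMNS <- c(
  "variant_id", "codon", "ref_aa", "alt_aa", "class",
  "rep", "count_t0", "count_tend", "libsize_t0", "libsize_tend"
)

#' Read a screen count table
#'
#' Reads the per-variant, per-replicate count TSV produced by
#' [write_counts_tsv()] (or mapped from AnalyzeSaturationMutagenesis-style
#' per-variant reports), validating the schema and rejecting malformed rows
#' with their line numbers.
#'
#' @param path Path to a tab-separated file with header columns
#'   `variant_id`, `codon`, `ref_aa`, `alt_aa`, `class`, `rep`, `count_t0`,
#'   `count_tend`, `libsize_t0`, `libsize_tend`.
#'
#' @return A typed tibble of screen counts.
#' @export
read_counts_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, COUNTS_COLUMNS, "counts file")
  num_cols <- c("codon", "rep", "count_t0", "count_tend",
    "libsize_t0", "libsize_tend")
  bad <- rep(FALSE, nrow(x))
  for (col in num_cols) {
    v <- x[[col]]
    bad <- bad | !is.numeric(v) | is.na(v) | v < 0
  }
  bad <- bad | !x$class %in% MUTATION_CLASSES
  if (any(bad)) {
    # +1 for the header line, matching what a user sees in the file.
    lines <- which(bad) + 1L
    abort(sprintf(
      "malformed row%s at line%s: %s (negative/missing numeric field or unknown class).",
      if (sum(bad) > 1L) "s" else "", if (sum(bad) > 1L) "s" else "",
      paste(head(lines, 10L), collapse = ", ")
    ))
  }
  x
}

#' @rdname read_counts_tsv
#' @param counts Count tibble (e.g. from [simulate_screen()]).
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  check_columns(counts, COUNTS_COLUMNS, "counts")
  readr::write_tsv(counts[, COUNTS_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Read and write BED-like interval files
#'
#' `read_bed()` accepts BED3/BED6 and narrowPeak (first 6 columns used) and
#' returns a 0-based half-open interval tibble; `write_bed()` writes BED3
#' plus optional name/score columns. Parsing is delegated to rtracklayer.
#'
#' @param path File path.
#' @return `read_bed()`: tibble with `chrom`, `start`, `end` and, when
#'   present, `name` and `score`.
#' @export
read_bed <- function(path) {
  n_fields <- length(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]])
  gr <- if (n_fields >= 10L) {
    rtracklayer::import(path, format = "BED", extraCols = c(
      signalValue = "numeric", pValue = "numeric",
      qValue = "numeric", peak = "integer"
    ))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  out <- from_granges0(gr)
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) out$name <- mc$name
  if ("score" %in% names(mc)) out$score <- as.numeric(mc$score)
  out
}

#' @rdname read_bed
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`).
#' @export
write_bed <- function(x, path) {
  check_columns(x, c("chrom", "start", "end"), "x")
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  if ("score" %in% cols && !"name" %in% cols) {
    x$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage parameter with the published default and a master
#' seed. The configuration round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param n_codons Codons in the simulated tile (used when no counts file is
#'   supplied). Default 200.
#' @param counts Optional path to a count TSV; when given, simulation is
#'   skipped.
#' @param pseudocount,normalize,window_radius,min_silent,sd_floor,min_replicates,lof_threshold
#'   Scoring parameters; see [dms_score()].
#' @param k_sd,min_subs Residue-profile parameters; see [residue_profile()].
#' @param seed Master seed for all randomness.
#' @param ... Overrides forwarded to [effect_model()] for the simulation
#'   stage (depth, doublings, lof_effect, ...).
#'
#' @return A `run_config` list.
#' @export
run_config <- function(n_codons = 200L,
                       counts = NULL,
                       pseudocount = 1,
                       normalize = TRUE,
                       window_radius = 2L,
                       min_silent = 2L,
                       sd_floor = 1e-6,
                       min_replicates = 1L,
                       lof_threshold = 2,
                       k_sd = 2,
                       min_subs = 1L,
                       seed = 1L,
                       ...) {
  model_args <- list(...)
  cfg <- list(
    n_codons = n_codons, counts = counts,
    pseudocount = pseudocount, normalize = normalize,
    window_radius = window_radius, min_silent = min_silent,
    sd_floor = sd_floor, min_replicates = min_replicates,
    lof_threshold = lof_threshold, k_sd = k_sd, min_subs = min_subs,
    seed = as.integer(seed), model = model_args
  )
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, c(
    raw[setdiff(names(raw), "model")],
    as.list(raw$model)
  ))
  cfg
}

#' Run the simulate-score-profile pipeline
#'
#' Executes the scoring pipeline end to end: load (or simulate) counts,
#' compute L2FCs and rolling-baseline z-scores, aggregate replicates, call
#' LOF variants, build the residue intolerance profile, the substitution
#' summary and the codon-by-substitution score matrix, and write everything
#' to `out_dir` together with a machine-readable run manifest (all
#' parameters, seed and package version). A fixed configuration yields
#' byte-identical score tables across runs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#'
#' @return Invisibly, a named list of output paths plus the in-memory
#'   `scores` tibble.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config().")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  counts <- stage("counts", {
    if (!is.null(config$counts)) {
      read_counts_tsv(config$counts)
    } else {
      model <- do.call(effect_model, modifyList(
        list(seed = config$seed), config$model
      ))
      lib <- simulate_library(config$n_codons, seed = config$seed)
      sim <- simulate_screen(lib, model)
      readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"),
        progress = FALSE)
      write_counts_tsv(sim$counts, file.path(out_dir, "counts.tsv"))
      sim$counts
    }
  })

  scores <- stage("scoring", dms_score(
    counts,
    pseudocount = config$pseudocount, normalize = config$normalize,
    window_radius = config$window_radius, min_silent = config$min_silent,
    sd_floor = config$sd_floor, min_replicates = config$min_replicates,
    lof_threshold = config$lof_threshold
  ))
  profile <- stage("residue_profile",
    residue_profile(scores, k_sd = config$k_sd, min_subs = config$min_subs))
  subs <- stage("substitution_summary", substitution_summary(scores))
  mat <- stage("score_matrix", score_matrix(scores))

  paths <- list(
    scores = file.path(out_dir, "scores.tsv"),
    residues = file.path(out_dir, "residues.tsv"),
    substitutions = file.path(out_dir, "substitutions.tsv"),
    matrix = file.path(out_dir, "score_matrix.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(as_tibble(scores), paths$scores, progress = FALSE)
  readr::write_tsv(profile, paths$residues, progress = FALSE)
  readr::write_tsv(subs, paths$substitutions, progress = FALSE)
  readr::write_tsv(mat, paths$matrix, progress = FALSE)
  jsonlite::write_json(
    list(
      package = "rollscreen",
      version = as.character(utils::packageVersion("rollscreen")),
      parameters = unclass(config),
      residue_cutoff = attr(profile, "cutoff")
    ),
    paths$manifest,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(list(paths = paths, scores = scores, profile = profile))
}
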