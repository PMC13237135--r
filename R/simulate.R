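#' Generate a saturation-mutagenesis variant library
#'
#' Builds the programmed variant set of a deep mutational scanning (DMS) tile:
#' for every codon, all 19 missense substitutions, one nonsense, one
#' frameshift, and one silent variant. A silent record is emitted at every
#' codon so that the rolling silent baseline used in scoring is defined along
#' the whole gene; sparser silent coverage (as in real libraries, where some
#' codons lack a synonymous single-nucleotide change) is exercised separately
#' through the window-expansion fallback of [rolling_silent_baseline()].
#'
#' @param n_codons Number of codons in the tile. Must be at least 5 so the
#'   default rolling window of 5 codons is defined.
#' @param seed Integer seed controlling the (arbitrary) wild-type residue
#'   assigned to each codon.
#'
#' @return A tibble with one row per programmed variant and columns
#'   `variant_id`, `codon` (1-based), `ref_aa`, `alt_aa` (one-letter amino
#'   acid, `"*"` for stop, `"fs"` for frameshift) and `class`
#'   (`silent`/`missense`/`nonsense`/`frameshift`); 22 rows per codon.
#' @examples
#' lib <- simulate_library(10, seed = 1)
#' table(lib$class)
#' @export
simulate_library <- function(n_codons, seed = 1L) {
  check_number(n_codons, "n_codons", lower = 5, integerish = TRUE)
  ref <- AA_ALPHABET[
    {
      old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      set.seed(as.integer(seed))
      idx <- sample.int(20L, n_codons, replace = TRUE)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      idx
    }
  ]
  per_codon <- function(codon) {
    r <- ref[codon]
    alt <- c(r, setdiff(AA_ALPHABET, r), STOP_TOKEN, FRAMESHIFT_TOKEN)
    cls <- c("silent", rep("missense", 19L), "nonsense", "frameshift")
    tibble(
      variant_id = paste0(r, codon, alt),
      codon = codon, ref_aa = r, alt_aa = alt, class = cls
    )
  }
  purrr::map_dfr(seq_len(n_codons), per_codon)
}

#' Define the effect model of a synthetic screen
#'
#' Parameters of the selection model used by [simulate_screen()]. Selection is
#' multiplicative on expected variant frequency: a variant with per-doubling
#' selection coefficient `s` (log2 enrichment units) changes its expected
#' frequency by `2^(doublings * s)` over the experiment. In a proliferation
#' screen against an antiproliferative protein, loss-of-function (LOF)
#' variants enrich, so LOF effects are positive.
#'
#' @param lof_effect Selection coefficient per population doubling (log2
#'   enrichment units) for true-LOF variants. Default 1.
#' @param lof_fraction_missense Fraction of missense variants planted as LOF,
#'   in `[0, 1]`.
#' @param terminal_escape_start Codon index after which nonsense and
#'   frameshift variants retain partial function (they receive
#'   `escape_factor * lof_effect` and truth class `"partial"`). `NULL`
#'   disables terminal escape.
#' @param escape_factor Multiplier on `lof_effect` for partial-function
#'   truncations. Default 0.5.
#' @param doublings Population doublings of selection between the two
#'   timepoints (the emulated screens span 4-8).
#' @param artifact_blocks Optional data frame with columns `codon_start`,
#'   `codon_end`, `shift`: contiguous codon blocks whose variants receive a
#'   constant additive shift (log2 units) on the log-scale end-timepoint
#'   expectation, emulating regional technical artifacts.
#' @param depth Total reads per sample (multinomial size). Default `1e6`.
#' @param n_replicates Number of independent replicate screens.
#' @param seed Master integer seed. Truth assignment and each replicate's
#'   count draws use child streams derived from it, so a fixed seed gives
#'   bit-identical output.
#'
#' @return An object of class `effect_model` (a named list).
#' @examples
#' effect_model(lof_effect = 1, doublings = 6, depth = 1e5, seed = 42)
#' @export
effect_model <- function(lof_effect = 1,
                         lof_fraction_missense = 0.05,
                         terminal_escape_start = NULL,
                         escape_factor = 0.5,
                         doublings = 6,
                         artifact_blocks = NULL,
                         depth = 1e6,
                         n_replicates = 3L,
                         seed = 1L) {
  check_number(lof_effect, "lof_effect")
  check_number(lof_fraction_missense, "lof_fraction_missense", lower = 0, upper = 1)
  check_number(escape_factor, "escape_factor")
  check_number(doublings, "doublings", lower = 0, strict_lower = TRUE)
  check_number(depth, "depth", lower = 0, strict_lower = TRUE)
  check_number(n_replicates, "n_replicates", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (!is.null(terminal_escape_start)) {
    check_number(terminal_escape_start, "terminal_escape_start",
      lower = 1, integerish = TRUE
    )
  }
  if (!is.null(artifact_blocks)) {
    check_columns(artifact_blocks, c("codon_start", "codon_end", "shift"),
      "artifact_blocks")
  }
  structure(
    list(
      lof_effect = lof_effect,
      lof_fraction_missense = lof_fraction_missense,
      terminal_escape_start = terminal_escape_start,
      escape_factor = escape_factor,
      doublings = doublings,
      artifact_blocks = artifact_blocks,
      depth = depth,
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model>\n")
  cat(sprintf(
    "  lof_effect: %g log2/doubling; lof_fraction_missense: %g\n",
    x$lof_effect, x$lof_fraction_missense
  ))
  cat(sprintf(
    "  doublings: %g; depth: %g reads; replicates: %d; seed: %d\n",
    x$doublings, x$depth, x$n_replicates, x$seed
  ))
  if (!is.null(x$terminal_escape_start)) {
    cat(sprintf(
      "  terminal escape after codon %d (factor %g)\n",
      x$terminal_escape_start, x$escape_factor
    ))
  }
  if (!is.null(x$artifact_blocks)) {
    cat(sprintf("  artifact blocks: %d\n", nrow(x$artifact_blocks)))
  }
  invisible(x)
}

# Assign a ground-truth class and per-doubling effect to every library variant.
assign_truth <- function(library, model) {
  set.seed(derive_seeds(model$seed, 1L))
  is_lof_missense <- library$class == "missense" &
    runif(nrow(library)) < model$lof_fraction_missense
  truncating <- library$class %in% c("nonsense", "frameshift")
  escaped <- if (is.null(model$terminal_escape_start)) {
    rep(FALSE, nrow(library))
  } else {
    truncating & library$codon > model$terminal_escape_start
  }
  true_class <- dplyr::case_when(
    escaped ~ "partial",
    truncating ~ "lof",
    is_lof_missense ~ "lof",
    TRUE ~ "neutral"
  )
  true_effect <- dplyr::case_when(
    true_class == "lof" ~ model$lof_effect,
    true_class == "partial" ~ model$escape_factor * model$lof_effect,
    TRUE ~ 0
  )
  tibble(
    variant_id = library$variant_id,
    true_class = true_class,
    true_effect = true_effect
  )
}

#' Simulate screen read counts with known ground truth
#'
#' Draws start-timepoint counts from a multinomial over uniform library
#' proportions at the configured depth, then end-timepoint counts from a
#' multinomial whose expected proportions are the start proportions scaled by
#' `2^(doublings * true_effect + artifact_shift)` and renormalized. Silent
#' variants are always neutral; a planted fraction of missense variants and
#' all truncating variants carry the LOF effect (optionally attenuated after
#' `terminal_escape_start`). Each replicate draws from its own RNG stream
#' derived from the master seed, so replicates are independent and the whole
#' simulation is reproducible bit-for-bit.
#'
#' @param library Variant library from [simulate_library()].
#' @param model An [effect_model()].
#'
#' @return A list with components `counts` (tibble: `variant_id`, `codon`,
#'   `ref_aa`, `alt_aa`, `class`, `rep`, `count_t0`, `count_tend`,
#'   `libsize_t0`, `libsize_tend`) and `truth` (tibble: `variant_id`,
#'   `true_class` in `neutral`/`lof`/`partial`, `true_effect` in log2
#'   enrichment units per doubling).
#' @examples
#' lib <- simulate_library(10)
#' sim <- simulate_screen(lib, effect_model(depth = 1e4, n_replicates = 2))
#' head(sim$counts)
#' @export
simulate_screen <- function(library, model) {
  check_columns(library, c("variant_id", "codon", "ref_aa", "alt_aa", "class"),
    "library")
  if (nrow(library) == 0L) abort("`library` must be nonempty.")
  if (!inherits(model, "effect_model")) {
    abort("`model` must be created by effect_model().")
  }
  if (!is.null(model$artifact_blocks)) {
    bad <- model$artifact_blocks$codon_start < min(library$codon) |
      model$artifact_blocks$codon_end > max(library$codon) |
      model$artifact_blocks$codon_start > model$artifact_blocks$codon_end
    if (any(bad)) abort("artifact blocks must lie within the gene.")
  }

  truth <- assign_truth(library, model)
  n <- nrow(library)
  depth <- model$depth

  shift <- rep(0, n)
  if (!is.null(model$artifact_blocks)) {
    for (i in seq_len(nrow(model$artifact_blocks))) {
      b <- model$artifact_blocks[i, ]
      in_block <- library$codon >= b$codon_start & library$codon <= b$codon_end
      shift[in_block] <- shift[in_block] + b$shift
    }
  }
  # Expected end-timepoint weight, log2 scale: selection plus regional artifact.
  log2_gain <- model$doublings * truth$true_effect + shift

  rep_seeds <- derive_seeds(model$seed + 1L, model$n_replicates)
  p0 <- rep(1 / n, n)
  counts <- purrr::map_dfr(seq_len(model$n_replicates), function(r) {
    set.seed(rep_seeds[r])
    c0 <- as.vector(rmultinom(1L, depth, p0))
    w <- p0 * 2^log2_gain
    c1 <- as.vector(rmultinom(1L, depth, w / sum(w)))
    tibble(
      variant_id = library$variant_id,
      codon = library$codon,
      ref_aa = library$ref_aa,
      alt_aa = library$alt_aa,
      class = library$class,
      rep = r,
      count_t0 = c0,
      count_tend = c1,
      libsize_t0 = depth,
      libsize_tend = depth
    )
  })
  list(counts = counts, truth = truth)
}
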