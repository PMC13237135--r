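#' Per-variant log2 fold-changes between screen timepoints
#'
#' Computes the log2 fold-change (L2FC) of each variant's read abundance
#' between the end and start of selection, per replicate. With
#' `normalize = TRUE` (default) counts are converted to library-proportions
#' first:
#' `L2FC = log2((count_tend + pc) / libsize_tend) - log2((count_t0 + pc) / libsize_t0)`.
#' The pseudocount keeps zero-count variants finite.
#'
#' @param counts Tibble of screen counts with columns `variant_id`, `rep`,
#'   `count_t0`, `count_tend` and, when `normalize = TRUE`, `libsize_t0` and
#'   `libsize_tend`. Extra columns (codon, class, ...) are carried through.
#' @param pseudocount Positive pseudocount added to both counts. Default 1.
#' @param normalize Divide by library sizes before taking the ratio.
#'
#' @return The input tibble with an `l2fc` column (log2 units) appended.
#' @examples
#' x <- tibble::tibble(
#'   variant_id = "v", rep = 1, count_t0 = 100, count_tend = 400,
#'   libsize_t0 = 1e6, libsize_tend = 1e6
#' )
#' compute_l2fc(x)$l2fc # log2(401/101)
#' @export
compute_l2fc <- function(counts, pseudocount = 1, normalize = TRUE) {
  check_columns(counts, c("variant_id", "rep", "count_t0", "count_tend"),
    "counts")
  check_number(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  if (any(counts$count_t0 < 0 | counts$count_tend < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative.")
  }
  if (normalize) {
    if (!all(c("libsize_t0", "libsize_tend") %in% names(counts))) {
      abort("`normalize = TRUE` requires `libsize_t0` and `libsize_tend` columns.")
    }
    dplyr::mutate(counts,
      l2fc = log2((.data$count_tend + pseudocount) / .data$libsize_tend) -
        log2((.data$count_t0 + pseudocount) / .data$libsize_t0)
    )
  } else {
    dplyr::mutate(counts,
      l2fc = log2((.data$count_tend + pseudocount) / (.data$count_t0 + pseudocount))
    )
  }
}

#' Rolling silent-variant baseline per codon and replicate
#'
#' For each codon and replicate, takes all silent variants whose codon lies
#' within `window_radius` positions (default +/-2, a 5-codon window, truncated
#' at the gene ends) and records the mean and sample standard deviation
#' (n - 1 denominator) of their L2FC values. A silent variant contributes to
#' the baseline of its own codon. If a window holds fewer than `min_silent`
#' silent variants it is expanded symmetrically one codon at a time until the
#' minimum is met; expanded windows are flagged in the output and reported via
#' a message. A gene with no silent variants at all is an error.
#'
#' @param l2fc Tibble from [compute_l2fc()]; must carry `codon`, `class`,
#'   `rep`, `l2fc`.
#' @param window_radius Codons on either side of the focal codon. Default 2.
#' @param min_silent Minimum silent variants per window before expansion.
#'   Default 2 (so a sample SD is always defined).
#'
#' @return Tibble with one row per (codon, rep): `baseline_mean`,
#'   `baseline_sd` (log2 units), `n_silent`, `radius` (radius actually used)
#'   and `expanded` (logical).
#' @export
rolling_silent_baseline <- function(l2fc, window_radius = 2L, min_silent = 2L) {
  check_columns(l2fc, c("codon", "class", "rep", "l2fc"), "l2fc")
  check_number(window_radius, "window_radius", lower = 1, integerish = TRUE)
  check_number(min_silent, "min_silent", lower = 1, integerish = TRUE)

  silent <- dplyr::filter(l2fc, .data$class == "silent", !is.na(.data$l2fc))
  if (nrow(silent) == 0L) {
    abort("no silent variants in the gene: the silent baseline is undefined.")
  }
  codons <- sort(unique(l2fc$codon))
  span <- range(codons)
  max_radius <- diff(span)

  out <- purrr::map_dfr(sort(unique(l2fc$rep)), function(r) {
    s <- dplyr::filter(silent, .data$rep == r)
    purrr::map_dfr(codons, function(cc) {
      radius <- window_radius
      repeat {
        x <- s$l2fc[s$codon >= cc - radius & s$codon <= cc + radius]
        if (length(x) >= min_silent || radius >= max_radius) break
        radius <- radius + 1L
      }
      tibble(
        codon = cc, rep = r,
        baseline_mean = if (length(x)) mean(x) else NA_real_,
        baseline_sd = sample_sd(x),
        n_silent = length(x),
        radius = radius,
        expanded = radius > window_radius
      )
    })
  })
  n_exp <- sum(out$expanded)
  if (n_exp > 0L) {
    inform(sprintf(
      "rolling baseline: %d window%s expanded beyond radius %d to reach %d silent variant%s.",
      n_exp, if (n_exp > 1L) "s were" else " was", window_radius,
      min_silent, if (min_silent > 1L) "s" else ""
    ))
  }
  out
}

#' Functional z-scores against the rolling silent baseline
#'
#' Standardizes each variant's L2FC against the silent baseline of its codon
#' and replicate: `z = (l2fc - baseline_mean) / baseline_sd`. Windows whose
#' baseline SD falls below `sd_floor` have the floor substituted and are
#' flagged (`sd_floored`); variants with no defined baseline get `NA` z
#' (rendered as missing downstream).
#'
#' @param l2fc Tibble from [compute_l2fc()] (needs `codon`, `rep`, `l2fc`).
#' @param baseline Tibble from [rolling_silent_baseline()].
#' @param sd_floor Lower guard on the baseline SD. Default `1e-6`.
#'
#' @return `l2fc` with `z` and `sd_floored` columns appended.
#' @export
score_replicates <- function(l2fc, baseline, sd_floor = 1e-6) {
  check_columns(l2fc, c("codon", "rep", "l2fc"), "l2fc")
  check_columns(baseline, c("codon", "rep", "baseline_mean", "baseline_sd"),
    "baseline")
  check_number(sd_floor, "sd_floor", lower = 0, strict_lower = TRUE)
  l2fc %>%
    left_join(
      select(baseline, "codon", "rep", "baseline_mean", "baseline_sd"),
      by = c("codon", "rep")
    ) %>%
    mutate(
      sd_floored = !is.na(.data$baseline_sd) & .data$baseline_sd < sd_floor,
      z = (.data$l2fc - .data$baseline_mean) /
        pmax(.data$baseline_sd, sd_floor)
    )
}

#' Aggregate replicate z-scores into final functional scores
#'
#' The final functional z-score of a variant is the arithmetic mean of its
#' per-replicate z-scores; the across-replicate sample SD measures
#' consistency. Variants scored in fewer than `min_replicates` replicates are
#' reported with `NA` mean (missing).
#'
#' @param scored Tibble from [score_replicates()].
#' @param min_replicates Minimum replicates with a defined z. Default 1.
#'
#' @return Tibble with one row per variant: identity columns present in the
#'   input (`codon`, `ref_aa`, `alt_aa`, `class` if available), `n_reps`,
#'   `mean_z`, `sd_z`.
#' @export
aggregate_scores <- function(scored, min_replicates = 1L) {
  check_columns(scored, c("variant_id", "rep", "z"), "scored")
  check_number(min_replicates, "min_replicates", lower = 1, integerish = TRUE)
  id_cols <- intersect(c("variant_id", "codon", "ref_aa", "alt_aa", "class"),
    names(scored))
  scored %>%
    group_by(across(all_of(id_cols))) %>%
    summarise(
      n_reps = sum(!is.na(.data$z)),
      mean_z = if (sum(!is.na(.data$z)) >= min_replicates) {
        mean(.data$z, na.rm = TRUE)
      } else {
        NA_real_
      },
      sd_z = sample_sd(.data$z),
      .groups = "drop"
    )
}

#' Score a screen end to end
#'
#' Convenience pipeline: [compute_l2fc()] -> [rolling_silent_baseline()] ->
#' [score_replicates()] -> [aggregate_scores()] -> [call_lof()]. Returns a
#' `dms_scores` tibble carrying the per-replicate scores as an attribute.
#'
#' @inheritParams compute_l2fc
#' @inheritParams rolling_silent_baseline
#' @inheritParams score_replicates
#' @inheritParams aggregate_scores
#' @param lof_threshold Strict lower bound on `mean_z` for a
#'   loss-of-function call. Default 2.
#'
#' @return A tibble of class `dms_scores`: one row per variant with `mean_z`,
#'   `sd_z`, `n_reps`, `lof`. Attributes: `replicate_scores` (per-replicate z
#'   table), `baseline`, `lof_threshold`.
#' @examples
#' sim <- simulate_screen(simulate_library(12), effect_model(depth = 5e4))
#' scores <- dms_score(sim$counts)
#' head(scores)
#' @export
dms_score <- function(counts,
                      pseudocount = 1,
                      normalize = TRUE,
                      window_radius = 2L,
                      min_silent = 2L,
                      sd_floor = 1e-6,
                      min_replicates = 1L,
                      lof_threshold = 2) {
  l2fc <- compute_l2fc(counts, pseudocount = pseudocount, normalize = normalize)
  baseline <- rolling_silent_baseline(l2fc,
    window_radius = window_radius, min_silent = min_silent
  )
  scored <- score_replicates(l2fc, baseline, sd_floor = sd_floor)
  out <- aggregate_scores(scored, min_replicates = min_replicates)
  out <- call_lof(out, threshold = lof_threshold)
  structure(out,
    class = c("dms_scores", class(out)),
    replicate_scores = scored,
    baseline = baseline,
    lof_threshold = lof_threshold
  )
}

#' Call loss-of-function variants
#'
#' A variant is called LOF when its final functional z-score strictly exceeds
#' the threshold (`mean_z > threshold`); at the default threshold of 2 this
#' corresponds to a two-sided normal tail probability of 0.0455. Variants at
#' exactly the threshold are not called. Missing scores give `NA`.
#'
#' @param scores Tibble with a `mean_z` column.
#' @param threshold LOF threshold on `mean_z`. Default 2.
#'
#' @return `scores` with a logical `lof` column.
#' @export
call_lof <- function(scores, threshold = 2) {
  check_columns(scores, "mean_z", "scores")
  check_number(threshold, "threshold")
  mutate(scores, lof = .data$mean_z > threshold)
}

#' Residue intolerance profile
#'
#' Averages the final z-scores of the observed missense substitutions at each
#' codon (stop and frameshift excluded) and flags intolerant residues: those
#' whose residue-average z strictly exceeds `mean + k_sd * SD` of the
#' residue averages, with mean and SD taken over residues having at least
#' `min_subs` scored substitutions (optionally restricted to residues with a
#' positive average via `positive_only`).
#'
#' @param scores A `dms_scores` tibble (or any tibble with `codon`, `class`,
#'   `mean_z`).
#' @param k_sd Number of SDs above the mean for the intolerance cutoff.
#'   Default 2.
#' @param min_subs Minimum scored substitutions for a residue to enter the
#'   cutoff computation. Default 1.
#' @param positive_only Compute the cutoff over residues with positive
#'   average z only. Default `FALSE` (all eligible residues).
#'
#' @return Tibble with one row per codon: `residue_mean_z`,
#'   `n_substitutions`, `intolerant`. The cutoff is attached as attribute
#'   `cutoff`.
#' @export
residue_profile <- function(scores, k_sd = 2, min_subs = 1L,
                            positive_only = FALSE) {
  check_columns(scores, c("codon", "class", "mean_z"), "scores")
  check_number(k_sd, "k_sd", lower = 0)
  check_number(min_subs, "min_subs", lower = 1, integerish = TRUE)
  prof <- scores %>%
    filter(.data$class == "missense") %>%
    group_by(.data$codon) %>%
    summarise(
      residue_mean_z = if (any(!is.na(.data$mean_z))) {
        mean(.data$mean_z, na.rm = TRUE)
      } else {
        NA_real_
      },
      n_substitutions = sum(!is.na(.data$mean_z)),
      .groups = "drop"
    )
  eligible <- prof$n_substitutions >= min_subs & !is.na(prof$residue_mean_z)
  if (positive_only) eligible <- eligible & prof$residue_mean_z > 0
  vals <- prof$residue_mean_z[eligible]
  cutoff <- if (length(vals) >= 2L) mean(vals) + k_sd * sample_sd(vals) else NA_real_
  prof <- mutate(prof,
    intolerant = !is.na(.data$residue_mean_z) & .data$residue_mean_z > cutoff
  )
  attr(prof, "cutoff") <- cutoff
  prof
}

#' Per-substitution deleteriousness summary
#'
#' Summarizes, for each substituted amino acid, the mean final z-score over
#' all residues and the number of residues at which that substitution is
#' severely deleterious (`mean_z` strictly above `threshold`).
#'
#' @param scores Tibble with `codon`, `alt_aa`, `class`, `mean_z`.
#' @param threshold Strict z threshold for the per-residue count. Default 2.
#'
#' @return Tibble with one row per substituted amino acid: `alt_aa`,
#'   `mean_z`, `n_residues`, `n_deleterious`.
#' @export
substitution_summary <- function(scores, threshold = 2) {
  check_columns(scores, c("codon", "alt_aa", "class", "mean_z"), "scores")
  scores %>%
    filter(.data$class == "missense") %>%
    group_by(.data$alt_aa) %>%
    summarise(
      n_residues = dplyr::n_distinct(.data$codon[!is.na(.data$mean_z)]),
      n_deleterious = dplyr::n_distinct(
        .data$codon[!is.na(.data$mean_z) & .data$mean_z > threshold]
      ),
      mean_z = mean(.data$mean_z, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    select("alt_aa", "mean_z", "n_residues", "n_deleterious") %>%
    arrange(dplyr::desc(.data$n_deleterious))
}

#' Codon-by-substitution score matrix
#'
#' Pivots final z-scores into a codon x substituted-amino-acid matrix for
#' heatmap rendering; silent variants appear in the reference residue's
#' column, stop and frameshift variants in dedicated `*` and `fs` columns.
#'
#' @param scores Tibble with `codon`, `alt_aa`, `mean_z`.
#' @return Tibble with one row per codon and one column per substitution.
#' @export
score_matrix <- function(scores) {
  check_columns(scores, c("codon", "alt_aa", "mean_z"), "scores")
  scores %>%
    select("codon", "alt_aa", "mean_z") %>%
    tidyr::pivot_wider(
      names_from = "alt_aa", values_from = "mean_z",
      names_sort = TRUE
    ) %>%
    arrange(.data$codon)
}
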