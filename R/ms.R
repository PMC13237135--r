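# Label-free proteomics statistics: log2 transform and missingness filter,
# down-shifted normal imputation (Perseus convention), and per-protein
# two-sample tests with dual significance criteria.

ms_sample_cols <- function(x) setdiff(names(x), "protein_id")

#' Log2 transform and missingness filter for LFQ intensities
#'
#' Log2-transforms present intensities and removes proteins quantified with
#' missing values in more than `max_missing` samples (counted across all
#' samples); a protein missing in exactly `max_missing` samples is retained.
#'
#' @param x Tibble with a `protein_id` column and one numeric intensity
#'   column per sample; `NA` marks a missing value. Present intensities must
#'   be positive.
#' @param max_missing Maximum tolerated missing values per protein.
#'   Default 3.
#'
#' @return Filtered tibble of log2 intensities.
#' @export
ms_preprocess <- function(x, max_missing = 3L) {
  check_columns(x, "protein_id", "x")
  check_number(max_missing, "max_missing", lower = 0, integerish = TRUE)
  samples <- ms_sample_cols(x)
  if (length(samples) == 0L) abort("`x` has no sample columns.")
  m <- as.matrix(x[, samples])
  if (any(m <= 0, na.rm = TRUE)) {
    abort("intensities must be positive where present.")
  }
  keep <- rowSums(is.na(m)) <= max_missing
  if (!any(keep)) abort("no proteins pass the missingness filter.")
  out <- x[keep, , drop = FALSE]
  out[samples] <- log2(m[keep, , drop = FALSE])
  as_tibble(out)
}

#' Down-shifted normal imputation of missing log2 intensities
#'
#' Replaces each missing value by a draw from a normal distribution shifted
#' into the low-intensity tail of its sample: mean
#' `mu_s - downshift * sigma_s` and SD `width * sigma_s`, where `mu_s` and
#' `sigma_s` are the observed mean and SD of that sample's column (the
#' Perseus convention of width and down shift as SD multiples). With
#' `mode = "absolute"` the width and down shift are instead absolute log2
#' units. Observed entries are never altered, and a fixed seed reproduces
#' the imputed matrix exactly.
#'
#' @param x Log2 intensity tibble from [ms_preprocess()].
#' @param width Imputation SD, as a multiple of the sample SD (default 0.3).
#' @param downshift Downward shift of the imputation mean, as a multiple of
#'   the sample SD (default 1.8).
#' @param seed Optional integer seed for reproducible draws.
#' @param mode `"sd_multiple"` (Perseus convention, default) or
#'   `"absolute"` (log2 units).
#'
#' @return Complete tibble with all missing values imputed.
#' @export
ms_impute <- function(x, width = 0.3, downshift = 1.8, seed = NULL,
                      mode = c("sd_multiple", "absolute")) {
  mode <- match.arg(mode)
  check_columns(x, "protein_id", "x")
  check_number(width, "width", lower = 0)
  check_number(downshift, "downshift")
  samples <- ms_sample_cols(x)
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (s in samples) {
    col <- x[[s]]
    miss <- is.na(col)
    if (!any(miss)) next
    obs <- col[!miss]
    if (length(obs) < 2L) {
      abort(sprintf(
        "sample `%s` has fewer than 2 observed values; cannot impute.", s
      ))
    }
    mu <- mean(obs)
    sigma <- stats::sd(obs)
    if (mode == "sd_multiple") {
      col[miss] <- stats::rnorm(sum(miss), mu - downshift * sigma, width * sigma)
    } else {
      col[miss] <- stats::rnorm(sum(miss), mu - downshift, width)
    }
    x[[s]] <- col
  }
  x
}

#' Per-protein differential abundance between two groups
#'
#' For each protein computes the log2 fold-change `meanA - meanB` (log2
#' space) and a two-tailed two-sample t test (pooled-variance Student test
#' by default, the Perseus convention; `welch = TRUE` for unequal
#' variances). A protein is significant only if `|l2fc| > fc_threshold` AND
#' `p < alpha`; no multiple-testing correction is applied. Proteins whose
#' values are constant in both groups are flagged `degenerate` with p
#' reported as 0 (nonzero difference) or 1 (zero difference).
#'
#' @param x Complete log2 intensity tibble (e.g. from [ms_impute()]).
#' @param groups Named character vector or tibble (`sample`, `group`)
#'   mapping sample columns to groups.
#' @param group_a,group_b The two group labels to compare (A minus B).
#' @param fc_threshold Minimum absolute log2 fold-change. Default 1.5.
#' @param alpha Significance level. Default 0.05.
#' @param welch Use Welch's unequal-variance t test. Default `FALSE`.
#'
#' @return Tibble with one row per protein: `protein_id`, `l2fc`, `t_stat`,
#'   `p_value`, `significant`, `degenerate`.
#' @export
ms_differential <- function(x, groups, group_a, group_b,
                            fc_threshold = 1.5, alpha = 0.05, welch = FALSE) {
  check_columns(x, "protein_id", "x")
  if (is.data.frame(groups)) {
    check_columns(groups, c("sample", "group"), "groups")
    groups <- setNames(as.character(groups$group), groups$sample)
  }
  samples_a <- names(groups)[groups == group_a]
  samples_b <- names(groups)[groups == group_b]
  samples_a <- intersect(samples_a, names(x))
  samples_b <- intersect(samples_b, names(x))
  if (length(samples_a) < 2L || length(samples_b) < 2L) {
    abort("each group needs at least two samples present in the matrix.")
  }
  ma <- as.matrix(x[, samples_a])
  mb <- as.matrix(x[, samples_b])
  if (anyNA(ma) || anyNA(mb)) {
    abort("the matrix contains missing values; run ms_impute() first.")
  }
  res <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    a <- ma[i, ]
    b <- mb[i, ]
    l2fc <- mean(a) - mean(b)
    degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (degenerate) {
      t_stat <- if (l2fc == 0) 0 else sign(l2fc) * Inf
      p <- if (l2fc == 0) 1 else 0
    } else {
      tt <- stats::t.test(a, b, var.equal = !welch)
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble(
      protein_id = x$protein_id[i], l2fc = l2fc, t_stat = t_stat,
      p_value = p,
      significant = abs(l2fc) > fc_threshold && p < alpha,
      degenerate = degenerate
    )
  })
  res
}
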