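#' Published binary thresholds for variant-effect predictors
#'
#' CADD scaled PHRED >= 20, REVEL >= 0.75 and AlphaMissense >= 0.564, the
#' calibrated cutoffs recommended by each tool's developers for a binary
#' pathogenic/benign classification.
#'
#' @return Named numeric vector of thresholds.
#' @export
predictor_thresholds <- function() {
  c(CADD = 20, REVEL = 0.75, AlphaMissense = 0.564)
}

#' Classify predictor scores as pathogenic or benign
#'
#' Applies the tool's published threshold with a non-strict comparison: a
#' score exactly at the threshold is pathogenic.
#'
#' @param score Numeric vector of predictor scores (PHRED scale for CADD,
#'   `[0, 1]` for REVEL and AlphaMissense).
#' @param tool One of `"CADD"`, `"REVEL"`, `"AlphaMissense"` (scalar or
#'   vector matching `score`).
#'
#' @return Character vector, `"pathogenic"` or `"benign"` (`NA` scores give
#'   `NA`).
#' @examples
#' classify_predictor(c(19.99, 20), "CADD")
#' classify_predictor(0.75, "REVEL")
#' @export
classify_predictor <- function(score, tool) {
  thresholds <- predictor_thresholds()
  if (!all(tool %in% names(thresholds))) {
    abort(sprintf(
      "unknown tool(s): %s. Supported: %s.",
      paste(setdiff(unique(tool), names(thresholds)), collapse = ", "),
      paste(names(thresholds), collapse = ", ")
    ))
  }
  unname(ifelse(score >= thresholds[tool], "pathogenic", "benign"))
}

#' Concordance between screen LOF calls and predictor calls
#'
#' Joins functional (DMS) calls with predictor calls on `variant_id` and
#' tabulates, per mutation class, the fraction of variants on which the two
#' binary classifications agree. Under the default `mode = "both"` a variant
#' is concordant when it is LOF in the screen and pathogenic by the
#' predictor, or non-LOF and benign; `mode = "pathogenic_only"` counts only
#' the LOF-and-pathogenic agreement as concordant.
#'
#' @param dms_calls Tibble with `variant_id`, logical `lof` and (optionally)
#'   `class`.
#' @param predictor_calls Tibble with `variant_id` and `call`
#'   (`"pathogenic"`/`"benign"`), e.g. from [classify_predictor()].
#' @param mode Concordance definition, see Details. Default `"both"`.
#'
#' @return Tibble with one row per mutation class (plus an `"all"` row when
#'   no class column is present): `n_concordant`, `n_total`, `percent`
#'   (`100 * n_concordant / n_total`, unrounded).
#' @examples
#' dms <- tibble::tibble(variant_id = c("a", "b"), class = "missense",
#'   lof = c(TRUE, FALSE))
#' pred <- tibble::tibble(variant_id = c("a", "b"),
#'   call = c("pathogenic", "pathogenic"))
#' concordance_by_class(dms, pred)
#' @export
concordance_by_class <- function(dms_calls, predictor_calls,
                                 mode = c("both", "pathogenic_only")) {
  mode <- match.arg(mode)
  check_columns(dms_calls, c("variant_id", "lof"), "dms_calls")
  check_columns(predictor_calls, c("variant_id", "call"), "predictor_calls")
  joined <- inner_join(
    dms_calls,
    select(predictor_calls, "variant_id", "call"),
    by = "variant_id"
  )
  joined <- filter(joined, !is.na(.data$lof), !is.na(.data$call))
  if (nrow(joined) == 0L) {
    abort("no variants shared between the DMS and predictor call sets.")
  }
  pathogenic <- joined$call == "pathogenic"
  joined$concordant <- if (mode == "both") {
    joined$lof == pathogenic
  } else {
    joined$lof & pathogenic
  }
  if (!"class" %in% names(joined)) joined$class <- "all"
  joined %>%
    group_by(.data$class) %>%
    summarise(
      n_concordant = sum(.data$concordant),
      n_total = n(),
      percent = 100 * .data$n_concordant / .data$n_total,
      .groups = "drop"
    )
}

#' Pathogenic fraction of a variant table
#'
#' The percentage of classified variants that are pathogenic, as used to
#' summarize ClinVar-style tables per gene.
#'
#' @param n_pathogenic Number of pathogenic variants (0 <= n <= total).
#' @param n_total Total classified variants (> 0).
#'
#' @return Percentage (`100 * n_pathogenic / n_total`), unrounded.
#' @examples
#' pathogenic_fraction(209, 5807)
#' @export
pathogenic_fraction <- function(n_pathogenic, n_total) {
  check_number(n_total, "n_total", lower = 0, strict_lower = TRUE,
    integerish = TRUE)
  check_number(n_pathogenic, "n_pathogenic", lower = 0, upper = n_total,
    integerish = TRUE)
  100 * n_pathogenic / n_total
}
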