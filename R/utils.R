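# Internal helpers shared across modules.

# One-letter amino acid alphabet (20 standard residues).
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

STOP_TOKEN <- "*"
FRAMESHIFT_TOKEN <- "fs"
MUTATION_CLASSES <- c("silent", "missense", "nonsense", "frameshift")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort(sprintf(
      "`%s` must be %s %s%s.", name,
      if (strict_lower) ">" else ">=", format(lower),
      if (is.finite(upper)) paste0(" and <= ", format(upper)) else ""
    ))
  }
  invisible(x)
}

check_columns <- function(x, cols, name = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame.", name))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column%s: %s.",
      name, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Derive independent child seeds from one master seed, without perturbing the
# caller's RNG state beyond the explicit set.seed call. Seeds stay below 2^31.
derive_seeds <- function(seed, n) {
  check_number(seed, "seed", integerish = TRUE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}
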