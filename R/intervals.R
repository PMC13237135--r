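# Interval algebra for peak workflows. All user-facing coordinates are BED
# convention: 0-based, half-open [start, end). Internally intervals are lifted
# to GenomicRanges (1-based, closed) for overlap and merge operations.

as_granges0 <- function(x, name = "intervals") {
  check_columns(x, c("chrom", "start", "end"), name)
  if (any(x$start < 0 | x$end <= x$start)) {
    abort(sprintf("`%s` must satisfy 0 <= start < end.", name))
  }
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = sort(unique(x$chrom))),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

from_granges0 <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Spike-in normalization factor
#'
#' Scale factor for spike-in normalized chromatin profiling signal:
#' `1 / ((ecoli_reads / human_reads) * 100)`, i.e. inversely proportional to
#' the fraction of reads aligning to the exogenous E. coli genome.
#'
#' @param ecoli_reads Uniquely aligned E. coli (spike-in) reads (> 0).
#' @param human_reads Uniquely aligned human reads (> 0).
#'
#' @return Scale factor (vectorized over inputs).
#' @examples
#' spikein_factor(100, 10000) # 1
#' @export
spikein_factor <- function(ecoli_reads, human_reads) {
  if (any(ecoli_reads <= 0) || any(human_reads <= 0)) {
    abort("read counts must be positive.")
  }
  1 / ((ecoli_reads / human_reads) * 100)
}

#' Merge overlapping or proximal intervals
#'
#' Unions intervals on the same chromosome whose gap is at most `distance`
#' base pairs (a gap of exactly `distance` merges, matching `bedtools merge
#' -d`); `distance = 0` merges overlapping and book-ended intervals. Output
#' is sorted and disjoint, so the operation is idempotent.
#'
#' @param x Interval tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param distance Maximum gap in bp. Default 0.
#'
#' @return Merged interval tibble.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1", start = c(10, 15),
#'   end = c(20, 30)))
#' @export
merge_intervals <- function(x, distance = 0L) {
  check_number(distance, "distance", lower = 0, integerish = TRUE)
  gr <- as_granges0(x)
  from_granges0(GenomicRanges::reduce(gr, min.gapwidth = distance + 1L))
}

#' Replicate-reproducible peaks
#'
#' Keeps intervals of `rep_a` that overlap (by at least 1 bp) any interval of
#' `rep_b` — the `bedtools intersect -u` convention — then sorts and merges
#' book-ended or overlapping survivors.
#'
#' @param rep_a,rep_b Interval tibbles (`chrom`, `start`, `end`).
#'
#' @return Merged tibble of reproducible intervals.
#' @export
reproducible_peaks <- function(rep_a, rep_b) {
  gr_a <- as_granges0(rep_a, "rep_a")
  gr_b <- as_granges0(rep_b, "rep_b")
  hit <- IRanges::overlapsAny(gr_a, gr_b)
  merge_intervals(from_granges0(gr_a[hit]), distance = 0L)
}

#' Partition consensus peaks into gained / lost / persistent
#'
#' Labels each consensus interval by overlap with differential-accessibility
#' region sets: `gained` if it overlaps any gained region, otherwise `lost`
#' if it overlaps any lost region, otherwise `persistent`. The gained-first
#' priority resolves the rare interval overlapping both sets (a message
#' reports how many); labels are mutually exclusive and exhaustive.
#'
#' @param consensus Consensus interval tibble (`chrom`, `start`, `end`).
#' @param gained,lost Differential region tibbles (same columns).
#'
#' @return `consensus` with a `label` factor column
#'   (`gained`/`lost`/`persistent`).
#' @export
partition_consensus <- function(consensus, gained, lost) {
  gr_c <- as_granges0(consensus, "consensus")
  hit_g <- if (nrow(gained)) {
    IRanges::overlapsAny(gr_c, as_granges0(gained, "gained"))
  } else {
    rep(FALSE, length(gr_c))
  }
  hit_l <- if (nrow(lost)) {
    IRanges::overlapsAny(gr_c, as_granges0(lost, "lost"))
  } else {
    rep(FALSE, length(gr_c))
  }
  both <- sum(hit_g & hit_l)
  if (both > 0L) {
    inform(sprintf(
      "%d consensus peak%s overlap both gained and lost regions; labelled gained (priority).",
      both, if (both > 1L) "s" else ""
    ))
  }
  mutate(consensus, label = factor(
    dplyr::case_when(hit_g ~ "gained", hit_l ~ "lost", TRUE ~ "persistent"),
    levels = c("gained", "lost", "persistent")
  ))
}

#' Quadrant concordance of paired log2 fold-changes
#'
#' Cross-tabulates the signs of paired fold-changes (e.g. differential
#' chromatin accessibility of a peak vs differential expression of its
#' annotated gene). Pairs with a zero fold-change on either axis are dropped
#' with a message (upstream effect-size filters normally preclude zeros).
#' Concordance is the fraction of pairs in the (+,+) and (-,-) quadrants.
#' The default `method = "signed"` runs a two-sided Fisher exact test on the
#' signed 2x2 table; `method = "observed_expected"` instead compares the
#' observed concordant/discordant split against an expected uniform 50/50
#' split of the same total. The odds ratio is the cross-product ratio of the
#' signed table, `Inf` when a discordant cell is empty.
#'
#' @param pairs Tibble with `l2fc_peak` and `l2fc_gene` columns (log2 units,
#'   finite).
#' @param method Test construction; see Details.
#'
#' @return Object of class `quadrant_test`: a list with `table` (2x2 signed
#'   counts), `n`, `n_dropped`, `concordance`, `odds_ratio`, `p_value`,
#'   `method` and the retained `pairs`. Has [tidy()], [glance()], `print()`
#'   and [autoplot()] methods.
#' @examples
#' set.seed(1)
#' pairs <- tibble::tibble(l2fc_peak = rnorm(50), l2fc_gene = rnorm(50))
#' quadrant_concordance(pairs)
#' @export
quadrant_concordance <- function(pairs, method = c("signed", "observed_expected")) {
  method <- match.arg(method)
  check_columns(pairs, c("l2fc_peak", "l2fc_gene"), "pairs")
  if (nrow(pairs) == 0L) abort("`pairs` must contain at least one pair.")
  if (any(!is.finite(pairs$l2fc_peak) | !is.finite(pairs$l2fc_gene))) {
    abort("fold-changes must be finite.")
  }
  keep <- pairs$l2fc_peak != 0 & pairs$l2fc_gene != 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(sprintf("dropped %d pair(s) with a zero fold-change.", n_dropped))
  }
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    abort("all pairs lie on an axis (zero fold-change); quadrants undefined.")
  }
  sp <- factor(ifelse(pairs$l2fc_peak > 0, "+", "-"), levels = c("+", "-"))
  sg <- factor(ifelse(pairs$l2fc_gene > 0, "+", "-"), levels = c("+", "-"))
  tab <- table(peak = sp, gene = sg)
  n <- sum(tab)
  concordant <- tab["+", "+"] + tab["-", "-"]
  discordant <- tab["+", "-"] + tab["-", "+"]
  odds_ratio <- if (discordant == 0) {
    if (concordant > 0) Inf else NaN
  } else if (tab["+", "-"] == 0 || tab["-", "+"] == 0) {
    Inf
  } else {
    (tab["+", "+"] * tab["-", "-"]) / (tab["+", "-"] * tab["-", "+"])
  }
  p_value <- if (method == "signed") {
    stats::fisher.test(tab)$p.value
  } else {
    half <- round(n / 2)
    stats::fisher.test(matrix(
      c(concordant, discordant, half, n - half), nrow = 2, byrow = TRUE
    ))$p.value
  }
  structure(
    list(
      table = tab, n = as.integer(n), n_dropped = as.integer(n_dropped),
      concordance = as.numeric(concordant) / n,
      odds_ratio = as.numeric(odds_ratio),
      p_value = p_value, method = method,
      pairs = as_tibble(pairs)
    ),
    class = "quadrant_test"
  )
}

#' @export
print.quadrant_test <- function(x, ...) {
  cat("<quadrant_test>  method:", x$method, "\n")
  print(x$table)
  cat(sprintf(
    "concordance: %.1f%% (%d/%d)  OR: %s  p: %.3g\n",
    100 * x$concordance, round(x$concordance * x$n), x$n,
    format(x$odds_ratio, digits = 4), x$p_value
  ))
  invisible(x)
}

#' @rdname quadrant_concordance
#' @param x A `quadrant_test` object.
#' @param ... Unused.
#' @export
tidy.quadrant_test <- function(x, ...) {
  tibble(
    n = x$n,
    n_concordant = as.integer(round(x$concordance * x$n)),
    concordance = x$concordance,
    percent = 100 * x$concordance,
    odds_ratio = x$odds_ratio,
    p_value = x$p_value,
    method = x$method
  )
}

#' @rdname quadrant_concordance
#' @export
glance.quadrant_test <- function(x, ...) tidy.quadrant_test(x)
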