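make_l2fc <- function(codon, class, rep, l2fc) {
  tibble::tibble(
    variant_id = paste0("v", seq_along(codon)),
    codon = codon, class = class, rep = rep, l2fc = l2fc
  )
}

test_that("log2 fold-change arithmetic matches direct computation and stays finite", {
  x <- tibble::tibble(
    variant_id = c("a", "b", "c"), rep = 1,
    count_t0 = c(100, 50, 10), count_tend = c(400, 50, 0),
    libsize_t0 = 1e6, libsize_tend = 1e6
  )
  out <- compute_l2fc(x, pseudocount = 1)
  expect_equal(out$l2fc[1], log2(401 / 101))
  expect_equal(out$l2fc[2], 0)
  expect_true(is.finite(out$l2fc[3]) && out$l2fc[3] < 0)

  # unequal library sizes enter through the proportion normalization
  y <- tibble::tibble(
    variant_id = "a", rep = 1, count_t0 = 100, count_tend = 100,
    libsize_t0 = 1e6, libsize_tend = 2e6
  )
  expect_equal(compute_l2fc(y)$l2fc, log2(101 / 2e6) - log2(101 / 1e6))

  # raw mode ignores library sizes
  expect_equal(compute_l2fc(x, normalize = FALSE)$l2fc[1], log2(401 / 101))
  expect_error(compute_l2fc(x[, setdiff(names(x), "libsize_t0")]), "libsize")
  expect_error(compute_l2fc(x, pseudocount = 0), "pseudocount")
})

test_that("rolling baseline reproduces hand-computed window statistics", {
  # three silents in the +/-2 window of codon 2, values {0, 1, 2}
  tbl <- make_l2fc(
    codon = c(1, 2, 3, 2), class = c("silent", "silent", "silent", "missense"),
    rep = 1, l2fc = c(0, 1, 2, 5)
  )
  b <- rolling_silent_baseline(tbl, window_radius = 2, min_silent = 2)
  row <- b[b$codon == 2, ]
  expect_equal(row$baseline_mean, 1)
  expect_equal(row$baseline_sd, 1)  # sample SD, n - 1 denominator
  expect_equal(row$n_silent, 3)

  tbl2 <- make_l2fc(rep(2, 3), rep("silent", 3), 1, c(1, 1, 1))
  b2 <- rolling_silent_baseline(tbl2, min_silent = 2)
  expect_equal(b2$baseline_mean[b2$codon == 2], 1)
  expect_equal(b2$baseline_sd[b2$codon == 2], 0)

  expect_error(
    rolling_silent_baseline(make_l2fc(1, "missense", 1, 0)),
    "silent"
  )
})

test_that("rolling baseline equals direct re-selection everywhere on a 50-codon gene", {
  set.seed(401)
  lib <- simulate_library(50, seed = 401)
  tbl <- tibble::tibble(
    variant_id = rep(lib$variant_id, 2),
    codon = rep(lib$codon, 2), class = rep(lib$class, 2),
    rep = rep(1:2, each = nrow(lib)),
    l2fc = rnorm(2 * nrow(lib))
  )
  b <- rolling_silent_baseline(tbl, window_radius = 2, min_silent = 2)
  for (r in 1:2) {
    for (cc in c(1, 2, 3, 17, 25, 48, 49, 50)) {
      o <- oracle_baseline(tbl, cc, r, radius = 2)
      row <- b[b$codon == cc & b$rep == r, ]
      expect_equal(row$baseline_mean, o$mean)
      expect_equal(row$baseline_sd, o$sd)
      expect_equal(row$n_silent, o$n)
    }
  }
})

test_that("sparse windows expand symmetrically until min_silent is reached", {
  # silents only at codons 1 and 10: the default window around codon 5 is empty
  tbl <- make_l2fc(
    codon = c(1, 10, 5), class = c("silent", "silent", "missense"),
    rep = 1, l2fc = c(0, 2, 1)
  )
  expect_message(
    b <- rolling_silent_baseline(tbl, window_radius = 2, min_silent = 2),
    "expanded"
  )
  row <- b[b$codon == 5, ]
  expect_true(row$expanded)
  expect_equal(row$n_silent, 2)
  expect_equal(row$baseline_mean, 1)
  # radius grew until both flanking silents were captured
  expect_gte(row$radius, 5)
})

test_that("z-scores follow the baseline standardization with an SD floor guard", {
  tbl <- make_l2fc(
    codon = c(1, 1, 1), class = c("silent", "silent", "missense"),
    rep = 1, l2fc = c(0.5, 1.5, 2.5)
  )
  b <- rolling_silent_baseline(tbl, min_silent = 2)
  z <- score_replicates(tbl, b)
  # baseline mean 1.0, SD sqrt(0.5); variant at 2.5
  expect_equal(z$z[3], (2.5 - 1) / sqrt(0.5))
  expect_false(any(z$sd_floored))

  # degenerate window (identical silents) trips the floor, never divides by 0
  tbl0 <- make_l2fc(
    codon = c(1, 1, 2), class = c("silent", "silent", "missense"),
    rep = 1, l2fc = c(1, 1, 3)
  )
  b0 <- rolling_silent_baseline(tbl0, min_silent = 2)
  z0 <- score_replicates(tbl0, b0, sd_floor = 1e-6)
  expect_true(z0$sd_floored[3])
  expect_equal(z0$z[3], 2 / 1e-6)
})

test_that("replicate aggregation averages defined z-scores and flags sparse variants", {
  scored <- tibble::tibble(
    variant_id = c("a", "a", "a", "b", "b", "c"),
    rep = c(1, 2, 3, 1, 2, 1),
    z = c(2, 2, 2, 1, 3, NA)
  )
  agg <- aggregate_scores(scored)
  expect_equal(agg$mean_z[agg$variant_id == "a"], 2)
  expect_equal(agg$sd_z[agg$variant_id == "a"], 0)
  expect_equal(agg$mean_z[agg$variant_id == "b"], 2)
  expect_equal(agg$sd_z[agg$variant_id == "b"], sd(c(1, 3)))
  expect_true(is.na(agg$mean_z[agg$variant_id == "c"]))

  agg2 <- aggregate_scores(scored, min_replicates = 3)
  expect_true(is.na(agg2$mean_z[agg2$variant_id == "b"]))
})

test_that("LOF calls use a strict threshold", {
  scores <- tibble::tibble(mean_z = c(2.0, 5.57, 0.985, 2.0001, NA))
  out <- call_lof(scores, threshold = 2)
  expect_identical(out$lof, c(FALSE, TRUE, FALSE, TRUE, NA))
})

test_that("z-scores are exactly invariant to block-constant shifts and global affine maps", {
  set.seed(77)
  lib <- simulate_library(40, seed = 77)
  sim <- simulate_screen(lib, effect_model(
    depth = 1e5, n_replicates = 2, seed = 78
  ))
  l2fc <- compute_l2fc(sim$counts)
  base_z <- score_replicates(l2fc, rolling_silent_baseline(l2fc))

  # additive constant on a contiguous codon block of one replicate: variants
  # whose whole window sits inside the block are unchanged
  shifted <- dplyr::mutate(l2fc,
    l2fc = l2fc + ifelse(rep == 1 & codon >= 10 & codon <= 25, 3.7, 0)
  )
  shift_z <- score_replicates(shifted, rolling_silent_baseline(shifted))
  interior <- base_z$codon >= 12 & base_z$codon <= 23
  expect_equal(shift_z$z[interior], base_z$z[interior])

  # global positive affine map leaves every z unchanged
  affine <- dplyr::mutate(l2fc, l2fc = 2.5 * l2fc - 1.3)
  affine_z <- score_replicates(affine, rolling_silent_baseline(affine))
  expect_equal(affine_z$z, base_z$z)
})

test_that("residue profile applies the mean + k.SD cutoff over residue averages", {
  # 99 residues at 0 and one at 10: sample SD 1, cutoff 0.1 + 2 = 2.1
  scores <- tibble::tibble(
    codon = 1:100, class = "missense", alt_aa = "A",
    mean_z = c(rep(0, 99), 10)
  )
  prof <- residue_profile(scores, k_sd = 2)
  expect_equal(attr(prof, "cutoff"), 0.1 + 2 * sd(c(rep(0, 99), 10)))
  expect_equal(which(prof$intolerant), 100)

  # identical residue averages: SD 0, strict > flags nothing
  flat <- tibble::tibble(
    codon = 1:10, class = "missense", alt_aa = "A", mean_z = 1
  )
  pflat <- residue_profile(flat)
  expect_false(any(pflat$intolerant))

  # stop/frameshift never enter residue averages
  mixed <- tibble::tibble(
    codon = rep(1:5, each = 3),
    class = rep(c("missense", "nonsense", "frameshift"), 5),
    alt_aa = rep(c("A", "*", "fs"), 5),
    mean_z = rep(c(1, 100, 100), 5)
  )
  pm <- residue_profile(mixed)
  expect_true(all(pm$residue_mean_z == 1))
  expect_true(all(pm$n_substitutions == 1))
})

test_that("planted intolerant residues are recovered exactly by the mean + 2SD rule", {
  set.seed(402)
  n_res <- 205
  planted <- c(30, 60, 90, 120, 150)
  scores <- tidyr::expand_grid(codon = 1:n_res, sub = 1:19) |>
    dplyr::mutate(
      class = "missense", alt_aa = "A",
      mean_z = rnorm(dplyr::n(), 0, 0.3) + ifelse(codon %in% planted, 4, 0)
    )
  prof <- residue_profile(scores, k_sd = 2)
  expect_setequal(prof$codon[prof$intolerant], planted)
})

test_that("substitution summary counts deleterious residues by brute-force tally", {
  set.seed(403)
  scores <- tidyr::expand_grid(codon = 1:30, alt_aa = c("P", "K", "G")) |>
    dplyr::mutate(
      class = "missense",
      mean_z = rnorm(dplyr::n()) + ifelse(alt_aa == "P" & codon <= 8, 5, 0)
    )
  out <- substitution_summary(scores, threshold = 2)
  # independent tally
  for (aa in c("P", "K", "G")) {
    expected <- length(unique(scores$codon[scores$alt_aa == aa & scores$mean_z > 2]))
    expect_equal(out$n_deleterious[out$alt_aa == aa], expected)
  }
  expect_equal(out$alt_aa[which.max(out$n_deleterious)], "P")

  none <- dplyr::mutate(scores, mean_z = 0)
  expect_true(all(substitution_summary(none)$n_deleterious == 0))
})

test_that("planted LOF variants are recovered with high sensitivity and low silent false-positive rate", {
  lib <- simulate_library(120, seed = 501)
  sim <- simulate_screen(lib, effect_model(
    lof_effect = 1, lof_fraction_missense = 0.08, doublings = 6,
    depth = 1e6, n_replicates = 3, seed = 502
  ))
  scores <- dms_score(sim$counts)
  joined <- dplyr::inner_join(
    tibble::as_tibble(scores), sim$truth, by = "variant_id"
  )
  sens <- mean(joined$lof[joined$true_class == "lof"], na.rm = TRUE)
  silent_fpr <- mean(joined$lof[joined$class == "silent"], na.rm = TRUE)
  expect_gte(sens, 0.9)
  expect_lte(silent_fpr, 0.05)
})
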