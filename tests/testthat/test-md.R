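frame_atoms <- function(frame, residue, x, element = "C", atom = "CA") {
  data.frame(
    frame = frame, residue = residue, atom = atom, element = element,
    x = x, y = 0, z = 0
  )
}

test_that("contact frequency counts frames with any heavy-atom pair strictly within the cutoff", {
  # one atom per residue, 3.5 apart in every frame
  f <- rbind(
    frame_atoms(1:4, 1, 0),
    frame_atoms(1:4, 10, 3.5)
  )
  out <- contact_frequency(f, group_a = 1, group_b = 10)
  expect_equal(out$f, 1)

  # contact in 3 of 4 frames
  f2 <- rbind(
    frame_atoms(1:4, 1, 0),
    frame_atoms(1:4, 10, c(3.5, 3.9, 2.0, 6.0))
  )
  expect_equal(contact_frequency(f2, 1, 10)$f, 0.75)

  # exactly at the cutoff is not a contact; hydrogens never count
  f3 <- rbind(
    frame_atoms(1, 1, 0),
    frame_atoms(1, 10, 4.0),
    frame_atoms(1, 10, 0.5, element = "H", atom = "1HG")
  )
  expect_equal(contact_frequency(f3, 1, 10)$f, 0)

  expect_error(contact_frequency(f, 1, 1), "disjoint")
  expect_error(contact_frequency(f, 1, 99), "no heavy atoms")
})

test_that("contact frequencies match an all-pairs brute-force scan on random coordinates", {
  set.seed(91)
  fr <- random_frames(n_frames = 5, n_atoms = 60, residues = 1:12)
  got <- contact_frequency(fr, group_a = 1:6, group_b = 7:12, cutoff = 4)
  exp <- oracle_contacts(fr, 1:6, 7:12, cutoff = 4)
  merged <- merge(got, exp, by = c("res1", "res2"))
  expect_equal(merged$f.x, merged$f.y)
  expect_true(all(got$f >= 0 & got$f <= 1))
})

test_that("frequency over concatenated frame sets is the frame-weighted mean of subsets", {
  set.seed(92)
  fr1 <- random_frames(4, 40, 1:8)
  fr2 <- random_frames(6, 40, 1:8)
  fr2$frame <- fr2$frame + 4
  f1 <- contact_frequency(fr1, 1:4, 5:8)
  f2 <- contact_frequency(fr2, 1:4, 5:8)
  fall <- contact_frequency(rbind(fr1, fr2), 1:4, 5:8)
  j <- merge(merge(f1, f2, by = c("res1", "res2"), all = TRUE),
    fall, by = c("res1", "res2"))
  j[is.na(j)] <- 0
  expect_equal(j$f, (4 * j$f.x + 6 * j$f.y) / 10)
})

test_that("energy differences follow the mutant-minus-reference convention", {
  expect_equal(delta_e(-10.0, -14.9), 4.9)
  expect_equal(delta_e(1:3, 1:3), c(0, 0, 0))
  expect_equal(delta_e(c(1, 2), c(3, 1)), -delta_e(c(3, 1), c(1, 2)))
  expect_error(delta_e(1:3, 1:2), "equal length")
})

test_that("control normalization subtracts matched replicates and is linear in the mean", {
  out <- ddelta(c(2, 2, 2), c(1, 1, 1))
  expect_equal(out$ddelta, c(1, 1, 1))
  expect_equal(attr(out, "mean"), 1)

  # a condition against itself is identically zero
  x <- tibble::tibble(replicate = 1:5, delta = rnorm(5))
  self <- ddelta(x, x)
  expect_true(all(self$ddelta == 0))

  set.seed(93)
  e <- tibble::tibble(replicate = 1:6, delta = rnorm(6))
  ctl <- tibble::tibble(replicate = 6:1, delta = rnorm(6))
  out2 <- ddelta(e, ctl)
  expect_equal(mean(out2$ddelta), mean(e$delta) - mean(ctl$delta))

  expect_error(
    ddelta(e, tibble::tibble(replicate = 2:7, delta = rnorm(6))),
    "do not match"
  )
})

test_that("one-sample dual-threshold significance matches the closed-form t distribution", {
  # symmetric values: t = 0, p = 1, not significant
  res0 <- one_sample_significance(c(-1, 1, -2, 2), 0.5)
  expect_equal(res0$t_stat, 0)
  expect_equal(res0$p_value, 1)
  expect_false(res0$significant)

  # n = 12 gives df = 11; t = mean/(sd/sqrt(n))
  set.seed(94)
  v <- rnorm(12, 1, 0.2)
  res <- one_sample_significance(v, 0.5)
  expect_equal(res$df, 11)
  expect_equal(res$t_stat, mean(v) / (sd(v) / sqrt(12)))
  expect_equal(res$p_value, t.test(v)$p.value)
  expect_true(res$significant)

  # textbook boundary: with df = 11, t = 2.201 sits at p = 0.05 two-sided
  expect_equal(2 * pt(2.201, 11, lower.tail = FALSE), 0.05, tolerance = 1e-3)

  # dual criteria: significant needs both p < alpha and |mean| > threshold
  small <- rnorm(12, 0.3, 0.01)
  res_small <- one_sample_significance(small, 0.5)
  expect_lt(res_small$p_value, 0.05)
  expect_false(res_small$significant)

  # electrostatic threshold of 1.0 can fail where VDW 0.5 passes
  mid <- rnorm(12, 0.8, 0.05)
  expect_true(one_sample_significance(mid, 0.5)$significant)
  expect_false(one_sample_significance(mid, 1.0)$significant)

  # zero SD is degenerate
  deg <- one_sample_significance(rep(2, 5), 0.5)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  expect_error(one_sample_significance(1, 0.5), "two replicate")
})

test_that("contact difference maps retain pairs beyond the loss threshold, gains reported separately", {
  grid <- tidyr::expand_grid(replicate = 1:3, res1 = 1:2, res2 = 10:11)
  f_of <- function(vals) dplyr::mutate(grid, f = vals[match(
    paste(res1, res2), c("1 10", "1 11", "2 10", "2 11")
  )])
  f_wt <- f_of(c(0.9, 0.8, 0.5, 0.2))
  f_mut <- f_of(c(0.4, 0.78, 0.9, 0.2))  # pair (1,10) lost, (2,10) gained
  f_ctrl <- dplyr::mutate(f_wt, f = f - 0.05) # control loses 0.05 everywhere

  out <- contact_diff_map(f_wt, f_mut, f_ctrl, loss_threshold = 0.2)
  lost <- out[out$change == "lost", ]
  gained <- out[out$change == "gained", ]
  expect_equal(nrow(lost), 1)
  expect_equal(c(lost$res1, lost$res2), c(1, 10))
  expect_equal(lost$mean_ddf, (0.9 - 0.4) - 0.05)
  expect_equal(c(gained$res1, gained$res2), c(2, 10))

  # identical maps yield an empty result
  empty <- contact_diff_map(f_wt, f_wt, f_ctrl = f_wt)
  expect_equal(nrow(empty), 0)

  # ddf is bounded in [-2, 2] whatever the inputs
  full_map <- attr(out, "map")
  expect_true(all(abs(full_map$mean_ddf) <= 2))

  # raw-loss mode filters on WT - mutant without control normalization
  raw <- contact_diff_map(f_wt, f_mut, f_ctrl, loss_threshold = 0.2, on = "df")
  expect_equal(raw$mean_df[raw$change == "lost"], 0.5)

  expect_error(
    contact_diff_map(f_wt, f_mut[-1, ], f_ctrl),
    "identical"
  )
})
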