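# Post-trajectory molecular dynamics statistics: contact frequencies between
# residue groups, interaction-energy differences with control-variant
# normalization, and dual-threshold significance calls. Energies are consumed
# as per-frame scalars from tables; running MD or computing force-field
# energies is out of scope.

#' Infer chemical element from an atom name
#'
#' Fallback for coordinate inputs lacking an element column: strips leading
#' digits and takes the first alphabetic character of the atom name (`"CA"`
#' -> `"C"`, `"1HG1"` -> `"H"`). Two-letter elements (e.g. metal ions) are
#' not resolved by this heuristic and should be supplied explicitly.
#'
#' @param atom_name Character vector of PDB-style atom names.
#' @return Character vector of one-letter element guesses.
#' @export
infer_element <- function(atom_name) {
  toupper(substr(gsub("^[^A-Za-z]+", "", atom_name), 1L, 1L))
}

#' Residue-pair contact frequencies across trajectory frames
#'
#' A residue pair (one residue from each group) is in contact in a frame when
#' any pair of heavy atoms (element not hydrogen) lies strictly within
#' `cutoff` angstroms; atoms at exactly the cutoff are not in contact. The
#' contact frequency is the fraction of frames in contact,
#' `f = n_contact / n_frames`, in `[0, 1]`.
#'
#' @param frames Tibble with columns `frame`, `residue`, `atom`, `element`,
#'   `x`, `y`, `z` (coordinates in angstroms). If `element` is absent it is
#'   inferred from `atom` via [infer_element()].
#' @param group_a,group_b Integer vectors of residue indices; must be
#'   disjoint and each must select at least one atom.
#' @param cutoff Contact distance in angstroms (strict `<`). Default 4.0.
#'
#' @return Tibble with one row per residue pair present in the groups:
#'   `res1` (from `group_a`), `res2` (from `group_b`), `n_contact`,
#'   `n_frames`, `f`.
#' @export
contact_frequency <- function(frames, group_a, group_b, cutoff = 4.0) {
  check_columns(frames, c("frame", "residue", "atom", "x", "y", "z"), "frames")
  check_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  if (length(intersect(group_a, group_b)) > 0L) {
    abort("`group_a` and `group_b` must be disjoint residue sets.")
  }
  if (!"element" %in% names(frames)) {
    frames$element <- infer_element(frames$atom)
  }
  heavy <- dplyr::filter(frames, toupper(.data$element) != "H")
  a <- dplyr::filter(heavy, .data$residue %in% group_a)
  b <- dplyr::filter(heavy, .data$residue %in% group_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    abort("a residue group selects no heavy atoms.")
  }
  frame_ids <- sort(unique(frames$frame))
  n_frames <- length(frame_ids)

  res_a <- sort(unique(a$residue))
  res_b <- sort(unique(b$residue))
  key <- function(r1, r2) paste(r1, r2, sep = "\r")
  all_pairs <- expand.grid(res1 = res_a, res2 = res_b,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hits <- setNames(integer(nrow(all_pairs)), key(all_pairs$res1, all_pairs$res2))

  for (fr in frame_ids) {
    fa <- a[a$frame == fr, , drop = FALSE]
    fb <- b[b$frame == fr, , drop = FALSE]
    if (nrow(fa) == 0L || nrow(fb) == 0L) next
    d2 <- outer(fa$x, fb$x, "-")^2 + outer(fa$y, fb$y, "-")^2 +
      outer(fa$z, fb$z, "-")^2
    in_contact <- d2 < cutoff^2
    if (!any(in_contact)) next
    idx <- which(in_contact, arr.ind = TRUE)
    pair_keys <- unique(key(fa$residue[idx[, 1L]], fb$residue[idx[, 2L]]))
    hits[pair_keys] <- hits[pair_keys] + 1L
  }
  tibble(
    res1 = all_pairs$res1,
    res2 = all_pairs$res2,
    n_contact = as.integer(hits[key(all_pairs$res1, all_pairs$res2)]),
    n_frames = n_frames,
    f = as.integer(hits[key(all_pairs$res1, all_pairs$res2)]) / n_frames
  )
}

#' Read trajectory frames from a multi-model PDB
#'
#' Parses a MODEL/ENDMDL multi-record PDB into the long frame table consumed
#' by [contact_frequency()], using the bio3d reader.
#'
#' @param path Path to a PDB file.
#' @return Tibble with `frame`, `residue`, `atom`, `element`, `x`, `y`, `z`.
#' @export
read_frames_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB frames requires the bio3d package.")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_atoms <- nrow(pdb$atom)
  element <- pdb$atom$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    element <- infer_element(pdb$atom$elety)
  }
  purrr::map_dfr(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    tibble(
      frame = i,
      residue = pdb$atom$resno,
      atom = pdb$atom$elety,
      element = element,
      x = m[, 1L], y = m[, 2L], z = m[, 3L]
    )
  })
}

#' Mean per-replicate interaction energy
#'
#' Averages per-frame interaction energies within each replicate (and
#' condition / residue pair where present), giving the per-replicate scalar
#' summaries that difference statistics operate on.
#'
#' @param energies Tibble with `replicate`, `frame`, `energy` and optionally
#'   `condition` and `pair_id` columns (energies in kcal/mol).
#' @return Tibble of per-replicate means (`mean_energy`).
#' @export
replicate_energy_means <- function(energies) {
  check_columns(energies, c("replicate", "frame", "energy"), "energies")
  grp <- intersect(c("replicate", "condition", "pair_id"), names(energies))
  energies %>%
    group_by(across(all_of(grp))) %>%
    summarise(
      mean_energy = mean(.data$energy), n_frames = n(), .groups = "drop"
    )
}

#' Mutant-minus-reference energy difference
#'
#' Plain per-replicate difference `delta_E = E_condition - E_reference`
#' (kcal/mol). With the convention that more negative interaction energies
#' are more favorable, positive values indicate a destabilizing change in
#' the condition of interest.
#'
#' @param mean_condition,mean_reference Numeric vectors of per-replicate mean
#'   energies, paired by position (replicate i with replicate i).
#' @return Numeric vector of differences.
#' @examples
#' delta_e(-10.0, -14.9) # 4.9, less favorable
#' @export
delta_e <- function(mean_condition, mean_reference) {
  if (length(mean_condition) != length(mean_reference)) {
    abort("per-replicate energy vectors must have equal length.")
  }
  mean_condition - mean_reference
}

#' Control-normalized difference-in-differences
#'
#' Subtracts a control variant's per-replicate differences from the
#' experimental mutant's, matching replicates by identifier, and averages:
#' the delta-delta statistic (energy or contact frequency) that removes
#' simulation-specific artifacts shared with the control.
#'
#' @param delta_exp,delta_control Tibbles with `replicate` and `delta`
#'   columns (or bare numeric vectors, matched by position).
#'
#' @return Tibble with `replicate`, `delta_exp`, `delta_control`, `ddelta`;
#'   the across-replicate mean is attached as attribute `mean` and returned
#'   by `mean()` of the `ddelta` column.
#' @export
ddelta <- function(delta_exp, delta_control) {
  to_tbl <- function(x, name) {
    if (is.data.frame(x)) {
      check_columns(x, c("replicate", "delta"), name)
      as_tibble(x[, c("replicate", "delta")])
    } else {
      tibble(replicate = seq_along(x), delta = as.numeric(x))
    }
  }
  e <- to_tbl(delta_exp, "delta_exp")
  ctl <- to_tbl(delta_control, "delta_control")
  if (nrow(e) != nrow(ctl) || !setequal(e$replicate, ctl$replicate)) {
    abort("experimental and control replicates do not match.")
  }
  out <- inner_join(
    rename(e, delta_exp = "delta"),
    rename(ctl, delta_control = "delta"),
    by = "replicate"
  ) %>%
    mutate(ddelta = .data$delta_exp - .data$delta_control)
  attr(out, "mean") <- mean(out$ddelta)
  out
}

#' One-sample significance with dual thresholds
#'
#' Two-tailed one-sample t test of per-replicate values against a zero null
#' (`t = mean / (SD / sqrt(n))`, n - 1 degrees of freedom), combined with an
#' effect-magnitude criterion: the result is significant only when
#' `p < alpha` AND `|mean| > magnitude_threshold`. A zero SD is degenerate;
#' the p-value is then reported as 0 (mean nonzero) or 1 (mean zero) and
#' flagged.
#'
#' @param values Numeric vector of per-replicate statistics (n >= 2), e.g.
#'   delta-delta energies in kcal/mol.
#' @param magnitude_threshold Minimum absolute mean for biological
#'   significance (0.5 kcal/mol for van der Waals energies, 1.0 for
#'   electrostatics, 0.2 for contact-frequency changes).
#' @param alpha Significance level. Default 0.05.
#'
#' @return One-row tibble of class `delta_result`: `estimate`, `sd`, `n`,
#'   `df`, `t_stat`, `p_value`, `magnitude_threshold`, `alpha`,
#'   `significant`, `degenerate`.
#' @examples
#' one_sample_significance(rnorm(12, mean = 1, sd = 0.2), 0.5)
#' @export
one_sample_significance <- function(values, magnitude_threshold, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) abort("at least two replicate values are required.")
  check_number(magnitude_threshold, "magnitude_threshold", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  m <- mean(values)
  s <- stats::sd(values)
  degenerate <- s == 0
  if (degenerate) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE)
  }
  out <- tibble(
    estimate = m, sd = s, n = n, df = n - 1L,
    t_stat = t_stat, p_value = p,
    magnitude_threshold = magnitude_threshold, alpha = alpha,
    significant = p < alpha && abs(m) > magnitude_threshold,
    degenerate = degenerate
  )
  class(out) <- c("delta_result", class(out))
  out
}

#' @rdname one_sample_significance
#' @param x A `delta_result`.
#' @param ... Unused.
#' @export
tidy.delta_result <- function(x, ...) as_tibble(unclass(x))

#' Control-normalized contact-difference map
#'
#' For each residue pair and replicate computes the contact loss
#' `delta_f = f_wt - f_mut` (positive when the mutant loses a contact present
#' in the wild type), subtracts the same quantity for a neutral control
#' variant, and averages over replicates. Pairs whose mean normalized loss
#' exceeds `loss_threshold` are reported as `lost`; pairs below
#' `-loss_threshold` (contacts gained) as `gained`. `on = "df"` filters on
#' the raw (un-normalized) wild-type-minus-mutant loss instead.
#'
#' @param f_wt,f_mut,f_ctrl Tibbles with `replicate`, `res1`, `res2`, `f`
#'   (from [contact_frequency()] run per replicate): wild type paired with
#'   the experimental mutant, the mutant itself, and the control variant.
#' @param f_wt_ctrl Wild-type frequencies paired with the control runs;
#'   defaults to `f_wt`.
#' @param loss_threshold Minimum mean (normalized) contact loss. Default 0.2.
#' @param on Filter on the control-normalized `"ddf"` (default) or raw
#'   `"df"` loss.
#'
#' @return Tibble of retained pairs: `res1`, `res2`, `mean_df`, `mean_ddf`,
#'   `change` (`"lost"`/`"gained"`). The full unfiltered map is attached as
#'   attribute `map`.
#' @export
contact_diff_map <- function(f_wt, f_mut, f_ctrl, f_wt_ctrl = NULL,
                             loss_threshold = 0.2, on = c("ddf", "df")) {
  on <- match.arg(on)
  check_number(loss_threshold, "loss_threshold", lower = 0)
  f_wt_ctrl <- f_wt_ctrl %||% f_wt
  cols <- c("replicate", "res1", "res2", "f")
  for (nm in c("f_wt", "f_mut", "f_ctrl", "f_wt_ctrl")) {
    check_columns(get(nm), cols, nm)
  }
  dom <- function(x) x[c("replicate", "res1", "res2")]
  same_domain <- function(a, b) {
    nrow(a) == nrow(b) &&
      nrow(dplyr::anti_join(dom(a), dom(b),
        by = c("replicate", "res1", "res2"))) == 0L
  }
  if (!same_domain(f_wt, f_mut) || !same_domain(f_wt, f_ctrl) ||
      !same_domain(f_wt, f_wt_ctrl)) {
    abort("contact maps must cover identical (replicate, residue pair) domains.")
  }
  joined <- f_wt %>%
    rename(f_wt = "f") %>%
    inner_join(rename(f_mut, f_mut = "f"), by = c("replicate", "res1", "res2")) %>%
    inner_join(rename(f_ctrl, f_ctrl = "f"), by = c("replicate", "res1", "res2")) %>%
    inner_join(rename(f_wt_ctrl, f_wt_ctrl = "f"),
      by = c("replicate", "res1", "res2")) %>%
    mutate(
      df = .data$f_wt - .data$f_mut,
      df_ctrl = .data$f_wt_ctrl - .data$f_ctrl,
      ddf = .data$df - .data$df_ctrl
    )
  map <- joined %>%
    group_by(.data$res1, .data$res2) %>%
    summarise(
      mean_df = mean(.data$df), mean_ddf = mean(.data$ddf),
      n_replicates = n(), .groups = "drop"
    )
  stat <- if (on == "ddf") map$mean_ddf else map$mean_df
  out <- map %>%
    mutate(change = dplyr::case_when(
      stat > loss_threshold ~ "lost",
      stat < -loss_threshold ~ "gained",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$change))
  attr(out, "map") <- map
  out
}
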