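# Independent brute-force oracles, deliberately naive: direct re-selection and
# all-pairs scans, kept free of the package's internal code paths.

# Rolling silent baseline by direct re-selection for one codon/replicate.
oracle_baseline <- function(l2fc_tbl, codon, rep_id, radius = 2) {
  s <- l2fc_tbl[l2fc_tbl$class == "silent" & l2fc_tbl$rep == rep_id &
    l2fc_tbl$codon >= codon - radius & l2fc_tbl$codon <= codon + radius, ]
  list(mean = mean(s$l2fc), sd = stats::sd(s$l2fc), n = nrow(s))
}

# Quadratic interval overlap: rows of `a` overlapping any row of `b`
# (0-based half-open).
oracle_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
}

# Quadratic merge with gap <= distance, per chromosome.
oracle_merge <- function(x, distance = 0) {
  out <- lapply(split(x, x$chrom), function(d) {
    d <- d[order(d$start, d$end), ]
    merged <- d[1, c("chrom", "start", "end")]
    for (i in seq_len(nrow(d))[-1]) {
      last <- nrow(merged)
      if (d$start[i] - merged$end[last] <= distance) {
        merged$end[last] <- max(merged$end[last], d$end[i])
      } else {
        merged <- rbind(merged, d[i, c("chrom", "start", "end")])
      }
    }
    merged
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c2 + d         # row 2 total
  k <- a + c2         # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All-pairs contact scan: residue pairs within cutoff in each frame.
oracle_contacts <- function(frames, group_a, group_b, cutoff = 4) {
  heavy <- frames[toupper(frames$element) != "H", ]
  a <- heavy[heavy$residue %in% group_a, ]
  b <- heavy[heavy$residue %in% group_b, ]
  frame_ids <- sort(unique(frames$frame))
  pairs <- expand.grid(
    res1 = sort(unique(a$residue)), res2 = sort(unique(b$residue))
  )
  f <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    hit <- 0L
    for (fr in frame_ids) {
      fa <- a[a$frame == fr & a$residue == pairs$res1[p], ]
      fb <- b[b$frame == fr & b$residue == pairs$res2[p], ]
      found <- FALSE
      for (i in seq_len(nrow(fa))) {
        for (j in seq_len(nrow(fb))) {
          d <- sqrt((fa$x[i] - fb$x[j])^2 + (fa$y[i] - fb$y[j])^2 +
            (fa$z[i] - fb$z[j])^2)
          if (d < cutoff) found <- TRUE
        }
      }
      if (found) hit <- hit + 1L
    }
    f[p] <- hit / length(frame_ids)
  }
  cbind(pairs, f = f)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 2000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(80L, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width
  )
}

random_frames <- function(n_frames, n_atoms, residues, box = 12) {
  do.call(rbind, lapply(seq_len(n_frames), function(fr) {
    data.frame(
      frame = fr,
      residue = sample(residues, n_atoms, replace = TRUE),
      atom = sample(c("CA", "CB", "N", "O", "1HG"), n_atoms, replace = TRUE),
      element = sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE),
      x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
      z = runif(n_atoms, 0, box)
    )
  }))
}
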