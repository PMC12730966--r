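# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorized code paths: sites by sliding window, counts
# by double loop, transitions by per-locus lookup.

naive_find_sites <- function(seq) {
  n <- nchar(seq)
  e <- integer(0)
  c4 <- integer(0)
  if (n >= 6) for (i in 1:(n - 5)) {
    if (substr(seq, i, i + 5) == "GAATTC") e <- c(e, i - 1L)
  }
  if (n >= 4) for (i in 1:(n - 3)) {
    if (substr(seq, i, i + 3) == "CCGG") c4 <- c(c4, i - 1L)
  }
  list(ecori = e, ccgg = c4)
}

naive_band_counts <- function(mat, samples) {
  counts <- c(I = 0L, II = 0L, III = 0L, IV = 0L)
  for (s in samples) {
    for (i in seq_len(nrow(mat))) {
      h <- mat[[paste0(s, "_H")]][i]
      m <- mat[[paste0(s, "_M")]][i]
      if (is.na(h) || is.na(m)) next
      ty <- if (h == 1 && m == 1) "I" else if (h == 1) "II"
            else if (m == 1) "III" else "IV"
      counts[ty] <- counts[ty] + 1L
    }
  }
  counts
}

naive_transition_counts <- function(ch, cm, th, tm) {
  counts <- integer(0)
  for (i in seq_along(ch)) {
    lab <- classify_transition(ch[i], cm[i], th[i], tm[i])
    counts[lab] <- (if (is.na(counts[lab])) 0L else counts[lab]) + 1L
  }
  counts
}

random_band_matrix <- function(n_loci, samples, p_na = 0) {
  mat <- data.frame(locus = paste0("L", seq_len(n_loci)),
                    stringsAsFactors = FALSE)
  for (s in samples) {
    for (lane in c("_H", "_M")) {
      v <- sample(0:1, n_loci, replace = TRUE)
      if (p_na > 0) v[runif(n_loci) < p_na] <- NA
      mat[[paste0(s, lane)]] <- v
    }
  }
  mat
}

# band matrix with exactly the requested marginal type counts for one sample
matrix_from_type_counts <- function(counts, sample = "CK") {
  pair <- list(I = c(1L, 1L), II = c(1L, 0L), III = c(0L, 1L),
               IV = c(0L, 0L))
  h <- integer(0)
  m <- integer(0)
  for (ty in names(pair)) {
    h <- c(h, rep(pair[[ty]][1], counts[[ty]]))
    m <- c(m, rep(pair[[ty]][2], counts[[ty]]))
  }
  out <- data.frame(locus = paste0("L", seq_along(h)),
                    stringsAsFactors = FALSE)
  out[[paste0(sample, "_H")]] <- h
  out[[paste0(sample, "_M")]] <- m
  out
}

# per-locus band pairs realizing given per-class transition counts
pairs_from_class_counts <- function(class_counts) {
  tab <- transition_patterns()
  idx <- rep(match(names(class_counts), tab$label), class_counts)
  list(ch = tab$ch[idx], cm = tab$cm[idx], th = tab$th[idx], tm = tab$tm[idx])
}

table3_class_counts <- c(A1 = 312, A2 = 24, A3 = 21,
                         B1 = 15, B2 = 4, B3 = 5, B4 = 9, B5 = 4,
                         C1 = 4, C2 = 6, C3 = 0, C4 = 0, C5 = 4, C6 = 1)

# all 16 flag combinations with the hand-derived expected band pair
flag_truth_table <- function() {
  g <- expand.grid(et = c(FALSE, TRUE), it = c(FALSE, TRUE),
                   eb = c(FALSE, TRUE), ib = c(FALSE, TRUE))
  # hand evaluation of the sensitivity rules, row by row:
  # HpaII cuts iff no internal 5mC and at most one external 5mC;
  # MspI cuts iff no external 5mC.
  g$h <- as.integer(!(g$it | g$ib) & (g$et + g$eb) <= 1)
  g$m <- as.integer(!(g$et | g$eb))
  g
}

# a more-methylated copy of a track: flags only ever added
upgrade_track <- function(track) {
  up <- track
  for (i in seq_len(nrow(up))) {
    s <- up$state[i]
    up$state[i] <- switch(s,
      UNMETHYLATED = sample(c("HEMI_EXTERNAL", "FULL_INTERNAL",
                              "FULL_EXTERNAL"), 1),
      HEMI_EXTERNAL = "FULL_EXTERNAL",
      FULL_INTERNAL = "FULL_EXTERNAL",
      s)
  }
  up
}

# interior cut positions implied by a fragment table, per sequence
cut_positions <- function(frags) {
  sort(unique(frags$end[frags$right_end %in% c("EcoRI", "HpaII", "MspI")]))
}

# synthetic Ct table from known per-condition fold changes (control = 1)
make_ct_table <- function(folds, n_bio = 3, n_tech = 2, noise_sd = 0,
                          ref_ct = 15, base_ct = 25) {
  rows <- list()
  for (cond in names(folds)) {
    for (b in seq_len(n_bio)) {
      sample_id <- paste(cond, b, sep = "_")
      dct_true <- (base_ct - ref_ct) - log2(folds[[cond]])
      bio_shift <- rnorm(1, 0, noise_sd)
      for (t in seq_len(n_tech)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample = sample_id, condition = cond, gene = "CwAACT",
          replicate = t, ct = ref_ct + dct_true + bio_shift)
        rows[[length(rows) + 1]] <- data.frame(
          sample = sample_id, condition = cond, gene = "rRNA18S",
          replicate = t, ct = ref_ct)
      }
    }
  }
  do.call(rbind, rows)
}
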