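# Synthetic genomes, methylomes, treatment kernels, rate recovery.

test_that("generate_genome meets its postconditions deterministically", {
  g1 <- generate_genome(10000, 0.5, n_ecori_min = 5, n_ccgg_min = 50,
                        seed = 1)
  expect_equal(nchar(g1), 10000L)
  sites <- naive_find_sites(substr(g1, 1, 2000))  # oracle spot check
  expect_equal(find_sites(substr(g1, 1, 2000)), sites)
  full <- find_sites(g1)
  expect_gte(length(full$ecori), 5L)
  expect_gte(length(full$ccgg), 50L)
  expect_identical(g1, generate_genome(10000, 0.5, 5, 50, seed = 1))
  expect_false(identical(g1, generate_genome(10000, 0.5, 5, 50, seed = 2)))
  # planting kicks in for motif-poor compositions
  g2 <- generate_genome(2000, 0.2, n_ecori_min = 10, n_ccgg_min = 40,
                        seed = 3)
  s2 <- find_sites(g2)
  expect_gte(length(s2$ecori), 10L)
  expect_gte(length(s2$ccgg), 40L)
  expect_error(generate_genome(1000, 0.5, 100, 200, seed = 1), "infeasible")
  expect_error(generate_genome(500, 0.5, 0, 0, seed = 1), "at least 1000")
})

test_that("generate_methylome draws i.i.d. states from the prior", {
  pos <- seq(0, 80290, by = 10)[1:8030]
  point <- c(UNMETHYLATED = 1, HEMI_EXTERNAL = 0, FULL_INTERNAL = 0,
             FULL_EXTERNAL = 0, ABSENT = 0)
  tr <- generate_methylome(pos, point, seed = 4)
  expect_true(all(tr$state == "UNMETHYLATED"))
  expect_equal(tr$start, as.integer(pos))

  prior <- default_state_prior()
  tr2 <- generate_methylome(pos, prior, seed = 5)
  expect_identical(tr2, generate_methylome(pos, prior, seed = 5))
  counts <- table(factor(tr2$state, levels = MSAP_STATES))
  expected <- length(pos) * prior
  sds <- sqrt(length(pos) * prior * (1 - prior))
  expect_true(all(abs(counts - expected) <= 4 * sds + 1e-9))
  expect_error(generate_methylome(pos, c(bogus = 1), seed = 1), "named")
})

test_that("the default prior folds the Type-IV mass as documented", {
  p <- default_state_prior()
  expect_equal(sum(p), 1)
  expect_equal(unname(p["UNMETHYLATED"]), 704 / 803)
  expect_equal(unname(p["FULL_EXTERNAL"] + p["ABSENT"]), 26 / 803)
  p2 <- default_state_prior(absent_frac = 0.5)
  expect_equal(unname(p2["ABSENT"]), 13 / 803)
})

test_that("apply_treatment follows the kernel", {
  track <- data.frame(seq_id = "s", start = 0:999,
                      state = rep(MSAP_STATES, each = 200))
  ident <- diag(5)
  dimnames(ident) <- list(MSAP_STATES, MSAP_STATES)
  expect_equal(apply_treatment(track, ident, seed = 1)$state, track$state)
  # forced demethylation of hemi sites
  force <- ident
  force["HEMI_EXTERNAL", ] <- c(1, 0, 0, 0, 0)
  out <- apply_treatment(track, force, seed = 2)
  expect_true(all(out$state[track$state == "HEMI_EXTERNAL"] ==
                    "UNMETHYLATED"))
  expect_equal(out$state[track$state != "HEMI_EXTERNAL"],
               track$state[track$state != "HEMI_EXTERNAL"])
  # kernel validation
  bad <- ident; bad["UNMETHYLATED", "ABSENT"] <- 0.1
  bad["UNMETHYLATED", "UNMETHYLATED"] <- 0.9
  expect_error(apply_treatment(track, bad, seed = 1), "ABSENT")
  bad2 <- ident; bad2[1, 1] <- 0.5
  expect_error(apply_treatment(track, bad2, seed = 1), "sum to 1")
})

test_that("default kernel reproduces the canonical rates in expectation", {
  k <- default_treatment_kernel()
  expect_equal(rowSums(k), setNames(rep(1, 5), MSAP_STATES))
  r <- kernel_rates(k, transition_state_prior())
  expect_equal(round_half_up(100 * r$no_change), 87.29)
  expect_equal(round_half_up(100 * r$d), 9.05)
  expect_equal(round_half_up(100 * r$m), 3.67)
  expect_equal(r$unclassified, 0)
})

test_that("make_kernel hits requested rates exactly, even when mass must be
           redistributed across source states", {
  rich <- c(UNMETHYLATED = 0.5, HEMI_EXTERNAL = 0.2, FULL_INTERNAL = 0.15,
            FULL_EXTERNAL = 0.15, ABSENT = 0)
  cases <- list(list(d = 0.0905, m = 0.0367, p = transition_state_prior()),
                list(d = 0.0905, m = 0.0367, p = default_state_prior()),
                list(d = 0.2, m = 0.1, p = rich),
                list(d = 0, m = 0.05, p = rich),
                list(d = 0.3, m = 0, p = rich))
  for (cs in cases) {
    k <- make_kernel(cs$d, cs$m, prior = cs$p)
    expect_equal(rowSums(k), setNames(rep(1, 5), MSAP_STATES))
    expect_true(all(k >= 0))
    r <- kernel_rates(k, cs$p)
    expect_equal(r$d, cs$d, tolerance = 1e-9)
    expect_equal(r$m, cs$m, tolerance = 1e-9)
  }
  # you cannot demethylate a genome that carries no methylation
  none <- c(UNMETHYLATED = 1, HEMI_EXTERNAL = 0, FULL_INTERNAL = 0,
            FULL_EXTERNAL = 0, ABSENT = 0)
  expect_error(make_kernel(0.1, 0, prior = none), "infeasible")
  expect_error(make_kernel(0.6, 0.5, prior = rich), "d \\+ m < 1")
})

test_that("recover_rates inverts the summary and quantifies uncertainty", {
  p <- pairs_from_class_counts(table3_class_counts)
  s <- transition_summary(p$ch, p$cm, p$th, p$tm)
  r <- recover_rates(s)
  expect_equal(round(r$d_hat, 4), 0.0905)
  expect_equal(round(r$m_hat, 4), 0.0367)
  expect_equal(r$n, 409L)
  expect_true(r$ci_d[1] < r$d_hat && r$d_hat < r$ci_d[2])
  expect_equal(r$se_d, sqrt(r$d_hat * (1 - r$d_hat) / 409))
  # identity kernel simulation recovers zero rates
  ident <- diag(5); dimnames(ident) <- list(MSAP_STATES, MSAP_STATES)
  s0 <- simulate_transitions(2000, kernel = ident, seed = 6)$summary
  r0 <- recover_rates(s0)
  expect_equal(c(r0$d_hat, r0$m_hat), c(0, 0))
})

test_that("parameter recovery is unbiased across the (d, m) grid", {
  # large demethylation rates need a methylation-rich starting population:
  # you cannot demethylate 20% of loci when only 3% carry methylation
  rich <- c(UNMETHYLATED = 0.5, HEMI_EXTERNAL = 0.2, FULL_INTERNAL = 0.15,
            FULL_EXTERNAL = 0.15, ABSENT = 0)
  n <- 10000
  cell <- 0
  for (d in c(0.02, 0.09, 0.2)) {
    for (m in c(0.01, 0.037, 0.1)) {
      cell <- cell + 1
      k <- make_kernel(d, m, prior = rich)
      r <- recover_rates(simulate_transitions(n, prior = rich, kernel = k,
                                              seed = 1000 + cell)$summary)
      expect_lt(abs(r$d_hat - d), 3 * sqrt(d * (1 - d) / n))
      expect_lt(abs(r$m_hat - m), 3 * sqrt(m * (1 - m) / n))
    }
  }
})

test_that("simulated transitions recover the kernel rates (single run)", {
  st <- simulate_transitions(10000, seed = 42)
  expect_identical(st$summary$class_counts,
                   simulate_transitions(10000, seed = 42)$summary$class_counts)
  r <- recover_rates(st$summary)
  expect_lt(abs(r$d_hat - 0.0905), 3 * sqrt(0.0905 * 0.9095 / 10000))
  expect_lt(abs(r$m_hat - 0.0367), 3 * sqrt(0.0367 * 0.9633 / 10000))
})

test_that("child-seed derivation is deterministic and spreads streams", {
  expect_identical(derive_seed(42, 1), derive_seed(42, 1))
  expect_false(derive_seed(42, 1) == derive_seed(42, 2))
  expect_false(derive_seed(42, 1) == derive_seed(43, 1))
  expect_true(derive_seed(.Machine$integer.max, 99) < 2^31)
})

test_that("simulate_msap_experiment is reproducible and self-consistent", {
  sim <- simulate_msap_experiment(seed = 9, n_bp = 8000, n_ecori_min = 15,
                                  n_ccgg_min = 40)
  sim2 <- simulate_msap_experiment(seed = 9, n_bp = 8000, n_ecori_min = 15,
                                   n_ccgg_min = 40)
  expect_identical(sim$matrix, sim2$matrix)
  expect_gt(nrow(sim$matrix), 0)
  # scored pairs match the planted states through the digestion engine
  states_c <- sim$control_track$state[match(sim$control$ccgg_start,
                                            sim$control_track$start)]
  want <- predict_bands(states_c)
  expect_equal(sim$control$h, want$h)
  expect_equal(sim$control$m, want$m)
  # the combined matrix round-trips through the scoring front end
  counts <- count_band_types(sim$matrix, "control")
  expect_equal(sum(counts), nrow(sim$matrix))
  # observed mode only reports loci visible on some gel
  obs <- simulate_msap_experiment(seed = 9, n_bp = 8000, n_ecori_min = 15,
                                  n_ccgg_min = 40,
                                  locus_universe = "observed")
  expect_gt(nrow(obs$matrix), 0)
  expect_true(all(obs$matrix$control_H + obs$matrix$control_M +
                  obs$matrix$treated_H + obs$matrix$treated_M > 0))
})

test_that("end-to-end digestion pipeline tracks the kernel rates loosely", {
  sim <- simulate_msap_experiment(seed = 31, n_bp = 60000,
                                  n_ecori_min = 150, n_ccgg_min = 300,
                                  prior = transition_state_prior())
  n <- sim$summary$n_classified
  expect_gt(n, 100)
  r <- recover_rates(sim$summary)
  expect_lt(abs(r$d_hat - 0.0905), 3 * sqrt(0.0905 * 0.9095 / n))
  expect_lt(abs(r$m_hat - 0.0367), 3 * sqrt(0.0367 * 0.9633 / n))
})
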