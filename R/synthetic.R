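# Synthetic genomes, methylomes and treatment kernels: the generative model
# the scoring pipeline assumes, used for round-trip and parameter-recovery
# testing. All randomness is driven by explicit seeds; child seeds are
# derived from the top-level seed by a fixed affine hash so that the
# sub-draws of a pipeline are independent but reproducible.

#' Derive a child seed from a top-level seed
#'
#' `(seed * 7919 + stream * 104729) mod (2^31 - 1)` -- a documented, fixed
#' splitting scheme so that each stochastic stage of a pipeline gets its own
#' reproducible stream from one user-facing seed.
#'
#' @param seed Integer top-level seed.
#' @param stream Integer stream index (1 = genome, 2 = methylome,
#'   3 = treatment, ...).
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed %% 2147483647L) * 7919 +
              as.double(stream) * 104729) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("an explicit integer seed is required")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a random genome with guaranteed restriction sites
#'
#' Draws an i.i.d. sequence at the requested GC content, then plants
#' additional `GAATTC` / `CCGG` motifs at random non-overlapping positions if
#' the random draw falls short of the requested minimum counts.
#' Deterministic given `seed`.
#'
#' @param n_bp Sequence length (>= 1000).
#' @param gc_content GC fraction in (0, 1).
#' @param n_ecori_min,n_ccgg_min Minimum number of EcoRI / CCGG sites.
#' @param seed Integer seed (required).
#' @return A character scalar DNA sequence.
#' @export
generate_genome <- function(n_bp, gc_content = 0.4, n_ecori_min = 0,
                            n_ccgg_min = 0, seed) {
  if (n_bp < 1000) stop("n_bp must be at least 1000")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  if (6 * n_ecori_min + 4 * n_ccgg_min > n_bp) {
    stop("infeasible motif density: requested motifs exceed sequence length")
  }
  .with_seed(seed, {
    probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
               G = gc_content / 2, T = (1 - gc_content) / 2)
    seq <- paste(sample(names(probs), n_bp, replace = TRUE, prob = probs),
                 collapse = "")
    for (round in 1:10) {
      sites <- find_sites(seq)
      need <- c(GAATTC = n_ecori_min - length(sites$ecori),
                CCGG = n_ccgg_min - length(sites$ccgg))
      if (all(need <= 0)) return(seq)
      # windows already holding a wanted motif must not be overwritten
      blocked <- c(unlist(lapply(sites$ecori, function(p) p:(p + 5))),
                   unlist(lapply(sites$ccgg, function(p) p:(p + 3))))
      for (motif in names(need)[need > 0]) {
        w <- nchar(motif)
        cand <- sample(0:(n_bp - w))
        placed <- 0L
        for (p in cand) {
          if (placed >= need[[motif]]) break
          win <- p:(p + w - 1)
          if (any(win %in% blocked)) next
          substr(seq, p + 1, p + w) <- motif
          blocked <- c(blocked, win)
          placed <- placed + 1L
        }
        if (placed < need[[motif]]) {
          stop("could not place the requested number of ", motif, " motifs")
        }
      }
    }
    stop("motif planting did not converge")  # nocov
  })
}

.check_prior <- function(prior) {
  if (is.null(names(prior)) || !all(names(prior) %in% MSAP_STATES)) {
    stop("prior must be named by the canonical states: ",
         paste(MSAP_STATES, collapse = ", "))
  }
  full <- setNames(numeric(5), MSAP_STATES)
  full[names(prior)] <- prior
  if (any(full < 0)) stop("prior probabilities must be non-negative")
  if (abs(sum(full) - 1) > 1e-6) stop("prior probabilities must sum to 1")
  full / sum(full)
}

#' Default CCGG state prior (control-like methylome)
#'
#' Frequencies matched to a typical untreated plant methylome as scored by
#' MSAP: Type I : II : III : IV band mass of 704 : 40 : 33 : 26 (out of 803).
#' The Type-IV mass covers both hypermethylation (`FULL_EXTERNAL`) and
#' fragment absence (`ABSENT`); `absent_frac` sets the share given to
#' `ABSENT` (default 0: all Type-IV mass is treated as hypermethylation,
#' since absent loci are invisible in a single-sample band matrix anyway).
#'
#' @param absent_frac Fraction of the Type-IV mass assigned to `ABSENT`.
#' @return Named probability vector over [MSAP_STATES].
#' @export
default_state_prior <- function(absent_frac = 0) {
  if (absent_frac < 0 || absent_frac > 1) {
    stop("absent_frac must be in [0, 1]")
  }
  p4 <- 26 / 803
  .check_prior(c(UNMETHYLATED = 704 / 803, HEMI_EXTERNAL = 40 / 803,
                 FULL_INTERNAL = 33 / 803,
                 FULL_EXTERNAL = (1 - absent_frac) * p4,
                 ABSENT = absent_frac * p4))
}

#' Control-state prior of the transition-scored locus population
#'
#' Marginal control-state frequencies of the locus population that enters
#' transition analysis (the loci classifiable into the fourteen classes):
#' 322 : 43 : 26 : 18 over unmethylated / hemi / internal-full /
#' external-full, out of 409. Under this prior the default treatment kernel
#' reproduces the canonical 87.29 / 9.05 / 3.67 no-change / demethylation /
#' methylation rates exactly in expectation.
#'
#' @return Named probability vector over [MSAP_STATES].
#' @export
transition_state_prior <- function() {
  .check_prior(c(UNMETHYLATED = 322 / 409, HEMI_EXTERNAL = 43 / 409,
                 FULL_INTERNAL = 26 / 409, FULL_EXTERNAL = 18 / 409,
                 ABSENT = 0))
}

.check_kernel <- function(kernel) {
  if (!is.matrix(kernel) || !identical(dim(kernel), c(5L, 5L)) ||
      !identical(rownames(kernel), MSAP_STATES) ||
      !identical(colnames(kernel), MSAP_STATES)) {
    stop("kernel must be a 5x5 matrix with rows and columns named by ",
         "the canonical states")
  }
  if (any(kernel < -1e-12)) stop("kernel probabilities must be non-negative")
  if (any(abs(rowSums(kernel) - 1) > 1e-8)) stop("kernel rows must sum to 1")
  if (abs(kernel["ABSENT", "ABSENT"] - 1) > 1e-12) {
    stop("ABSENT must be absorbing (a missing fragment cannot reappear)")
  }
  if (any(kernel[MSAP_STATES != "ABSENT", "ABSENT"] > 1e-12)) {
    stop("no state may transition into ABSENT (fragment presence is ",
         "time-invariant within an individual)")
  }
  kernel
}

# The eleven labeled state transitions carrying demethylation (B1-B5) and
# methylation (C1-C6) mass, in table order.
.KERNEL_TRANSITIONS <- data.frame(
  label = c("B1", "B2", "B3", "B4", "B5", "C1", "C2", "C3", "C4", "C5", "C6"),
  category = c(rep("DEMETHYLATION", 5), rep("METHYLATION", 6)),
  from = c("HEMI_EXTERNAL", "FULL_INTERNAL", "FULL_EXTERNAL",
           "FULL_EXTERNAL", "FULL_EXTERNAL",
           "UNMETHYLATED", "UNMETHYLATED", "UNMETHYLATED",
           "HEMI_EXTERNAL", "HEMI_EXTERNAL", "FULL_INTERNAL"),
  to = c("UNMETHYLATED", "UNMETHYLATED", "UNMETHYLATED",
         "HEMI_EXTERNAL", "FULL_INTERNAL",
         "HEMI_EXTERNAL", "FULL_INTERNAL", "FULL_EXTERNAL",
         "FULL_INTERNAL", "FULL_EXTERNAL", "FULL_EXTERNAL"),
  stringsAsFactors = FALSE)

#' Default treatment transition kernel (demethylating agent)
#'
#' Per-state transition probabilities of a demethylating treatment,
#' calibrated to the empirical class counts of a 5-azacytidine exposure:
#' B1..B5 = 15,4,5,9,4 demethylation events and C1..C6 = 4,6,0,0,4,1
#' methylation events over 409 classified loci, turned into row-conditional
#' probabilities by the control-state marginals (322, 43, 26, 18). Under
#' [transition_state_prior()] the expected demethylation and methylation
#' rates are 9.05% and 3.67% of classified loci. `ABSENT` is absorbing.
#'
#' @return 5x5 row-stochastic matrix over [MSAP_STATES].
#' @export
default_treatment_kernel <- function() {
  k <- diag(5)
  dimnames(k) <- list(MSAP_STATES, MSAP_STATES)
  counts <- c(15, 4, 5, 9, 4, 4, 6, 0, 0, 4, 1)
  marg <- c(UNMETHYLATED = 322, HEMI_EXTERNAL = 43,
            FULL_INTERNAL = 26, FULL_EXTERNAL = 18, ABSENT = 1)
  for (i in seq_len(nrow(.KERNEL_TRANSITIONS))) {
    tr <- .KERNEL_TRANSITIONS[i, ]
    k[tr$from, tr$to] <- counts[i] / marg[[tr$from]]
  }
  diag(k) <- 0
  diag(k) <- 1 - rowSums(k)
  .check_kernel(k)
}

#' Build a treatment kernel with target demethylation/methylation rates
#'
#' Constructs a transition kernel whose expected demethylation and
#' methylation rates over classified loci equal `d` and `m` when loci start
#' from `prior`. The rate mass is distributed over the five demethylation
#' and six methylation transitions proportionally to `b_weights` /
#' `c_weights` (defaults: the empirical 15:4:5:9:4 and 4:6:0:0:4:1),
#' subject to feasibility: a source state cannot emit more transition mass
#' than its prior frequency. Excess mass of an over-subscribed source is
#' redistributed to the remaining transitions of the same category; if the
#' prior cannot carry the requested rates at all, an error is raised (you
#' cannot demethylate loci that are not methylated).
#'
#' Loci that start `FULL_EXTERNAL` and do not transition stay invisible
#' (`IV -> IV` is unclassifiable), as do `ABSENT` loci; the solver accounts
#' for their exclusion from the rate denominator.
#'
#' @param d,m Target demethylation / methylation rates in `[0, 1)` (fraction
#'   of classified loci).
#' @param prior Control-state prior the kernel will be applied to.
#' @param b_weights,c_weights Relative weights of the B1..B5 and C1..C6
#'   transitions.
#' @return 5x5 row-stochastic matrix with attributes `d`, `m`, `prior`.
#' @export
make_kernel <- function(d, m, prior = transition_state_prior(),
                        b_weights = c(15, 4, 5, 9, 4),
                        c_weights = c(4, 6, 0, 0, 4, 1)) {
  if (d < 0 || m < 0 || d + m >= 1) stop("need d >= 0, m >= 0, d + m < 1")
  p <- .check_prior(prior)
  tr <- .KERNEL_TRANSITIONS
  w <- c(b_weights, c_weights)
  if (length(w) != nrow(tr) || any(w < 0)) {
    stop("b_weights and c_weights must be non-negative, lengths 5 and 6")
  }
  fe_b <- which(tr$from == "FULL_EXTERNAL")
  u <- p[["ABSENT"]] + p[["FULL_EXTERNAL"]]  # worst-case unclassified mass
  for (outer in 1:200) {
    mass <- .allocate_masses(d * (1 - u), m * (1 - u), p, tr, w)
    u_new <- p[["ABSENT"]] + (p[["FULL_EXTERNAL"]] - sum(mass[fe_b]))
    if (abs(u_new - u) < 1e-13) break
    u <- u_new
  }
  k <- diag(5)
  dimnames(k) <- list(MSAP_STATES, MSAP_STATES)
  diag(k) <- 1
  for (i in seq_len(nrow(tr))) {
    if (mass[i] == 0) next
    k[tr$from[i], tr$to[i]] <- k[tr$from[i], tr$to[i]] + mass[i] / p[[tr$from[i]]]
  }
  diag(k) <- 0
  diag(k) <- pmax(0, 1 - rowSums(k))
  k <- .check_kernel(k)
  structure(k, d = d, m = m, prior = p)
}

# Proportional allocation of unconditional transition masses with per-source
# caps (a state cannot transition more often than it occurs). Over-cap
# sources are frozen at their cap and the deficit is redistributed within
# the same category.
.allocate_masses <- function(target_b, target_c, prior, tr, w) {
  target <- c(DEMETHYLATION = target_b, METHYLATION = target_c)
  mass <- numeric(nrow(tr))
  for (cc in names(target)) {
    i <- tr$category == cc & w > 0
    if (target[[cc]] > 0) {
      if (!any(i)) stop("no transitions available to carry ", cc, " mass")
      mass[i] <- target[[cc]] * w[i] / sum(w[i])
    }
  }
  frozen <- rep(FALSE, nrow(tr))
  for (iter in 1:20) {
    row_tot <- tapply(mass, tr$from, sum)
    caps <- prior[names(row_tot)]
    over <- names(row_tot)[row_tot > caps + 1e-12]
    if (length(over) == 0) return(mass)
    for (s in over) {
      i_all <- tr$from == s
      i_free <- i_all & !frozen
      avail <- prior[[s]] - sum(mass[i_all & frozen])
      cur <- sum(mass[i_free])
      if (avail < -1e-12 || (cur == 0 && avail < 0)) {
        stop("requested rates are infeasible under this prior")
      }
      scale <- if (cur > 0) max(0, avail) / cur else 0
      mass[i_free] <- mass[i_free] * scale
      frozen[i_free] <- TRUE
    }
    for (cc in names(target)) {
      i_cc <- tr$category == cc
      need <- target[[cc]] - sum(mass[i_cc])
      if (need > 1e-15) {
        j <- i_cc & !frozen & w > 0
        if (!any(j)) {
          stop("requested ", tolower(cc), " rate is infeasible under this ",
               "prior: not enough source-state mass")
        }
        mass[j] <- mass[j] + need * w[j] / sum(w[j])
      }
    }
  }
  stop("mass allocation did not converge")  # nocov
}

#' Expected transition rates of a kernel under a prior
#'
#' Analytic expectation of the no-change / demethylation / methylation rates
#' over classified loci: each (control state, treated state) pair is mapped
#' through [predict_bands()] and [classify_transition()], joint masses are
#' summed by category, and unclassifiable pairs (e.g. `FULL_EXTERNAL`
#' staying, or anything involving `ABSENT`) are excluded from the
#' denominator.
#'
#' @param kernel 5x5 transition kernel.
#' @param prior Control-state prior.
#' @return List `no_change`, `d`, `m` (fractions of classified loci) and
#'   `unclassified` (fraction of all loci).
#' @export
kernel_rates <- function(kernel, prior = transition_state_prior()) {
  kernel <- .check_kernel(kernel)
  p <- .check_prior(prior)
  from_bands <- predict_bands(MSAP_STATES)
  cat_mass <- c(NO_CHANGE = 0, DEMETHYLATION = 0, METHYLATION = 0,
                UNCLASSIFIED = 0)
  for (i in seq_along(MSAP_STATES)) {
    for (j in seq_along(MSAP_STATES)) {
      mass <- p[[i]] * kernel[i, j]
      if (mass == 0) next
      lab <- classify_transition(from_bands$h[i], from_bands$m[i],
                                 from_bands$h[j], from_bands$m[j])
      cat_mass[[transition_category(lab)]] <-
        cat_mass[[transition_category(lab)]] + mass
    }
  }
  classified <- sum(cat_mass[1:3])
  if (classified == 0) stop("no classified mass under this prior/kernel")
  list(no_change = cat_mass[["NO_CHANGE"]] / classified,
       d = cat_mass[["DEMETHYLATION"]] / classified,
       m = cat_mass[["METHYLATION"]] / classified,
       unclassified = cat_mass[["UNCLASSIFIED"]])
}

#' Draw a methylome track over CCGG sites
#'
#' Independent categorical state per site (no spatial correlation -- a
#' documented simplification), deterministic given `seed`.
#'
#' @param ccgg_positions Integer vector of 0-based CCGG starts.
#' @param prior Named state prior (see [default_state_prior()]).
#' @param seed Integer seed.
#' @param seq_id Sequence name for the track records.
#' @return Methylome track data.frame: `seq_id`, `start`, `state`.
#' @export
generate_methylome <- function(ccgg_positions, prior = default_state_prior(),
                               seed, seq_id = "seq1") {
  p <- .check_prior(prior)
  states <- .with_seed(seed, {
    sample(MSAP_STATES, length(ccgg_positions), replace = TRUE, prob = p)
  })
  data.frame(seq_id = rep(seq_id, length(ccgg_positions)),
             start = as.integer(ccgg_positions),
             state = states, stringsAsFactors = FALSE)
}

#' Apply a treatment transition kernel to a methylome track
#'
#' Independent per-site draw from the kernel row of the current state;
#' deterministic given `seed`.
#'
#' @param track Methylome track (see [generate_methylome()]).
#' @param kernel 5x5 transition kernel (see [default_treatment_kernel()]).
#' @param seed Integer seed.
#' @return A methylome track with updated states.
#' @export
apply_treatment <- function(track, kernel = default_treatment_kernel(),
                            seed) {
  kernel <- .check_kernel(kernel)
  bad <- setdiff(unique(track$state), MSAP_STATES)
  if (length(bad) > 0) {
    stop("track contains unknown state(s): ", paste(bad, collapse = ", "))
  }
  out <- track
  .with_seed(seed, {
    for (s in unique(track$state)) {
      idx <- which(track$state == s)
      out$state[idx] <- sample(MSAP_STATES, length(idx), replace = TRUE,
                               prob = kernel[s, ])
    }
  })
  out
}

#' Estimate treatment rates from a transition summary
#'
#' Method-of-moments inverse of the treatment kernel's summary scalars: the
#' class-B and class-C fractions estimate the demethylation and methylation
#' probability mass, with binomial standard-error confidence intervals.
#'
#' @param summary A [transition_summary()] result.
#' @param conf Confidence level for the intervals.
#' @return List with `d_hat`, `m_hat`, `se_d`, `se_m`, `ci_d`, `ci_m`,
#'   `n` (classified loci).
#' @export
recover_rates <- function(summary, conf = 0.95) {
  if (!inherits(summary, "transition_summary")) {
    stop("summary must be a transition_summary object")
  }
  n <- summary$n_classified
  if (n == 0) stop("no classified loci")
  d_hat <- summary$demethylation_pct / 100
  m_hat <- summary$methylation_pct / 100
  z <- qnorm(1 - (1 - conf) / 2)
  se <- function(p) sqrt(p * (1 - p) / n)
  ci <- function(p) pmin(1, pmax(0, p + c(-1, 1) * z * se(p)))
  list(d_hat = d_hat, m_hat = m_hat, se_d = se(d_hat), se_m = se(m_hat),
       ci_d = ci(d_hat), ci_m = ci(m_hat), n = n, conf = conf)
}

#' Simulate locus transitions at the state level
#'
#' Fast generative model without the digestion step: control states are
#' drawn from `prior`, treated states from `kernel`, both are rendered into
#' band pairs by [predict_bands()] and summarised by [transition_summary()].
#'
#' @param n_loci Number of CCGG loci.
#' @param prior Control-state prior.
#' @param kernel Treatment transition kernel.
#' @param seed Integer seed.
#' @return List with `summary` ([transition_summary()]), `control_states`,
#'   `treated_states`.
#' @export
simulate_transitions <- function(n_loci, prior = transition_state_prior(),
                                 kernel = default_treatment_kernel(), seed) {
  p <- .check_prior(prior)
  control <- .with_seed(derive_seed(seed, 2), {
    sample(MSAP_STATES, n_loci, replace = TRUE, prob = p)
  })
  track <- data.frame(seq_id = "virtual", start = seq_len(n_loci) - 1L,
                      state = control, stringsAsFactors = FALSE)
  treated <- apply_treatment(track, kernel, derive_seed(seed, 3))$state
  cb <- predict_bands(control)
  tb <- predict_bands(treated)
  list(summary = transition_summary(cb$h, cb$m, tb$h, tb$m),
       control_states = control, treated_states = treated)
}

#' Simulate a full paired MSAP experiment
#'
#' Generates a genome, a control methylome, a treated methylome (via the
#' kernel), digests both lanes at both timepoints, selects resolvable bands,
#' scores them and summarises the transitions.
#'
#' Two locus universes are available. `"candidate"` (default) scores against
#' every potential EcoRI--CCGG fragment of the fully cleaved genome; each
#' locus then reflects exactly the state of its defining CCGG site, which is
#' what parameter-recovery studies need. `"observed"` scores against the
#' union of bands actually present on any of the four gels -- realistic, but
#' it includes composite fragments that span an uncut (methylated) internal
#' CCGG, whose presence depends on other sites' states, and it drops loci
#' invisible at both timepoints.
#'
#' @param seed Integer seed driving all stages (see [derive_seed()]).
#' @param n_bp,gc_content,n_ecori_min,n_ccgg_min Genome parameters
#'   ([generate_genome()]).
#' @param prior Control-state prior ([generate_methylome()]).
#' @param kernel Treatment kernel ([apply_treatment()]).
#' @param min_len,max_len,gel_mode Band selection and comigration options.
#' @param locus_universe `"candidate"` or `"observed"` (see Details).
#' @return List: `genome` (named character), `control_track`,
#'   `treated_track`, `control`, `treated` (scored locus tables), `matrix`
#'   (combined band matrix with `control_H/M`, `treated_H/M` columns),
#'   `summary` ([transition_summary()]), `params`.
#' @export
simulate_msap_experiment <- function(seed, n_bp = 20000, gc_content = 0.5,
                                     n_ecori_min = 10, n_ccgg_min = 60,
                                     prior = default_state_prior(),
                                     kernel = default_treatment_kernel(),
                                     min_len = 50, max_len = 700,
                                     gel_mode = FALSE,
                                     locus_universe = c("candidate",
                                                        "observed")) {
  locus_universe <- match.arg(locus_universe)
  seq <- generate_genome(n_bp, gc_content, n_ecori_min, n_ccgg_min,
                         seed = derive_seed(seed, 1))
  genome <- c(chr1 = seq)
  ccgg <- find_sites(seq)$ccgg
  control_track <- generate_methylome(ccgg, prior, derive_seed(seed, 2),
                                      seq_id = "chr1")
  treated_track <- apply_treatment(control_track, kernel,
                                   derive_seed(seed, 3))
  band_set <- function(track, lane) {
    select_bands(digest_genome(genome, track, lane), min_len, max_len)
  }
  sets <- list(band_set(control_track, "hpaii"),
               band_set(control_track, "mspi"),
               band_set(treated_track, "hpaii"),
               band_set(treated_track, "mspi"))
  loci <- if (locus_universe == "candidate") {
    candidate_loci(genome, min_len, max_len)
  } else {
    .union_loci(sets)
  }
  control <- bands_to_matrix(sets[[1]], sets[[2]], loci, gel_mode)
  treated <- bands_to_matrix(sets[[3]], sets[[4]], loci, gel_mode)
  combined <- data.frame(locus = loci$locus,
                         control_H = control$h, control_M = control$m,
                         treated_H = treated$h, treated_M = treated$m,
                         stringsAsFactors = FALSE)
  list(genome = genome,
       control_track = control_track, treated_track = treated_track,
       control = control, treated = treated, matrix = combined,
       summary = transition_summary(control$h, control$m,
                                    treated$h, treated$m,
                                    locus = loci$locus),
       params = list(seed = seed, n_bp = n_bp, gc_content = gc_content,
                     prior = .check_prior(prior), kernel = kernel,
                     min_len = min_len, max_len = max_len,
                     gel_mode = gel_mode, locus_universe = locus_universe))
}
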