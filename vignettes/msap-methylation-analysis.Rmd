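---
title: "MSAP methylation analysis with msapkit: model, assumptions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSAP methylation analysis with msapkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapkit)
```

## The assay and its observable

Methylation-sensitive amplified polymorphism (MSAP) reads genome-wide
cytosine methylation at CCGG sites without a reference genome. Genomic DNA
is digested twice: once with EcoRI + HpaII and once with EcoRI + MspI. HpaII
and MspI are isoschizomers — both recognise CCGG — but they respond
differently to 5-methylcytosine, so a locus's band is present in one lane,
both, or neither depending on the methylation configuration of its CCGG
duplex. After adapter ligation and selective PCR, fragments are resolved on
a PAGE gel and scored 1/0 per locus and lane.

A CCGG duplex carries four potentially methylated cytosines: the external
(5′) and internal (3′) C on each strand. `msapkit` keeps this full
four-flag representation and reduces it through one decision table:

* **HpaII** cleaves iff no internal cytosine is methylated **and** at most
  one external cytosine is methylated (it tolerates hemi-methylation of the
  external C, and is blocked by full external methylation or any internal
  methylation);
* **MspI** cleaves iff no external cytosine is methylated (it is indifferent
  to internal methylation).

A band is present in a lane iff the enzyme cleaves: the scored fragment is
the EcoRI–HpaII/MspI piece, which only exists when the
methylation-sensitive cut is made. The four canonical states map to the four
observable band types:

| state | HpaII | MspI | type | reading |
|---|---|---|---|---|
| unmethylated | 1 | 1 | I | no methylation |
| hemi-external | 1 | 0 | II | hemi-methylation |
| full internal | 0 | 1 | III | internal full methylation |
| full external | 0 | 0 | IV | hypermethylation — or no fragment at all |

Type IV is ambiguous by construction (`classify_state(0, 0)` returns both
`FULL_EXTERNAL` and `ABSENT`); every other pair has a unique preimage. The
decision table is total over all 16 flag combinations (plus `ABSENT`), and
all 16 rows are frozen by hand in the test suite. Published descriptions of
the two enzymes' sensitivities are not always internally consistent; the
table above is the one that makes the Type I–IV reading self-consistent and
matches canonical MSAP usage, and it is the single source of truth for every
module here (classification, digestion, simulation).

## Group statistics

`count_band_types()` pools (locus × sample) cells for a sample group and
`methylation_ratios()` computes, over `total = I + II + III + IV`:
total methylated `(II+III+IV)/total`, fully methylated `(III+IV)/total`,
hemi-methylated `II/total`, non-methylated `I/total`, each × 100. The MSAP
polymorphism percentage is numerically the same statistic as the total
methylated ratio; both names are exposed. Internal values are never rounded;
reporting rounds half-away-from-zero to 2 decimals (`round_half_up()`, with
a 1e-8 guard against binary representation error at exact ties) because
that is how such tables are printed.

Cells with a missing lane are excluded pairwise and counted in
`n_excluded` — the assay has no missing-data convention, and silent NaN
propagation hides fixture bugs, so an all-zero group is an error
("no scorable loci"), not a NaN.

```{r ratios}
methylation_ratios(c(704, 40, 33, 26))
```

## Transition classes between control and treated samples

Comparing one consensus band pair per locus between a control and a treated
sample gives 16 possible pattern pairs, 14 of which carry standard labels:
A1–A3 (no change), B1–B5 (demethylation), C1–C6 (methylation). Under the
total methylation-load order I < II < III < IV, every B class strictly
decreases and every C class strictly increases — a property test asserts
this. The two unlabeled pairs, III → II and IV → IV, are reported as
`UNCLASSIFIED` with their locus ids and excluded from the rate denominator:
the three printed rates of such tables are only reproducible with the
denominator equal to the sum over the 14 classes, so this convention is
asserted rather than assumed. Replicated gels are pooled per group by
majority vote (`consensus_bands()`), ties becoming missing.

```{r transitions}
s <- transition_summary_from_counts(
  c(A1 = 312, A2 = 24, A3 = 21, B1 = 15, B2 = 4, B3 = 5, B4 = 9, B5 = 4,
    C1 = 4, C2 = 6, C3 = 0, C4 = 0, C5 = 4, C6 = 1))
round_half_up(c(s$no_change_pct, s$demethylation_pct, s$methylation_pct))
```

## In silico digestion

`digest_genome()` cuts at every `GAATTC` (EcoRI, methylation-insensitive,
G|AATTC) and at every `CCGG` whose tracked state permits the lane's enzyme
(C|CGG). Only fragment lengths matter downstream, so overhang bookkeeping is
by convention. Coordinates are 0-based half-open internally and BED-like in
files. `select_bands()` models the amplification chemistry (one EcoRI end,
one HpaII/MspI end) and the gel window; the default window [50, 700] bp is a
typical PAGE-resolvable range — the source gels' scored range is not
published, so this is a package default, configurable and not calibrated.

Two invariants anchor the engine: every base lies in exactly one fragment
per lane (conservation), and adding methylation never creates a cut, so a
more methylated track's cut set is a subset (monotonicity). Both are
property-tested over 200 random genomes.

**Locus identity.** Each CCGG site can define a scorable locus on either
side (wherever its neighbouring cut is EcoRI). In exact mode, loci are
(sequence, start, end) identities; in `gel_mode`, fragments comigrate by
length, so equal-length fragments in a lane merge into one band — the
realistic ambiguity a gel scorer faces. Round-trip identifiability
(simulate → digest → score → classify recovers the planted state's band
type) holds at every locus in exact mode and at every unique-length locus in
gel mode; both are acceptance-tested.

**Candidate vs observed universes.** A partial digest also produces
*composite* fragments spanning an uncut (methylated) internal CCGG; their
presence depends on other sites' states. Scoring against the union of
observed bands (what a real gel gives you) therefore mixes these in, while
scoring against the fully-cut *candidate* universe gives exact per-site
correspondence. `simulate_msap_experiment()` defaults to the candidate
universe — the right choice for parameter recovery — and offers
`locus_universe = "observed"` for realism; the candidate universe also
represents hypermethylated-throughout loci as IV → IV (excluded as
unclassifiable), which the observed universe never sees at all.

## The generative model

`generate_genome()` draws an i.i.d. sequence at a requested GC content and
plants any shortfall of `GAATTC`/`CCGG` motifs at random non-overlapping
positions. `generate_methylome()` draws one state per CCGG site i.i.d. from
a categorical prior — real methylomes are spatially autocorrelated, so this
is a stated simplification: green tests establish the scoring arithmetic and
estimator calibration, not spatial realism. `apply_treatment()` moves each
site independently through a transition kernel. All stages take explicit
seeds; one top-level seed is split into per-stage child seeds by a fixed
affine hash (`derive_seed()`), so runs are bit-for-bit reproducible.

**Priors.** Two defaults are shipped because the two published tables they
mirror describe different locus populations:

* `default_state_prior()` — a control methylome as MSAP scores it:
  704 : 40 : 33 : 26 over types I–IV (of 803). The Type-IV mass covers both
  hypermethylation and fragment absence; `absent_frac` (default 0) sets the
  split, which is unobservable in a single-sample matrix.
* `transition_state_prior()` — the control marginals of the
  transition-scored population: 322 : 43 : 26 : 18 (of 409). This
  population is markedly more methylated than the group-level one (IV mass
  4.4% vs 3.2%, II 10.5% vs 5.0%); the group-level prior mathematically
  cannot produce the canonical transition rates (below), so transition
  simulations default to this prior.

**Kernel.** `default_treatment_kernel()` uses the empirical conditional
transition frequencies of a 5-azacytidine exposure (B1..B5 = 15,4,5,9,4;
C1..C6 = 4,6,0,0,4,1 over 409 loci). Under `transition_state_prior()` its
expected rates are exactly 87.29% / 9.05% / 3.67% no-change /
demethylation / methylation — `kernel_rates()` computes this expectation
analytically, and the `ABSENT` row is absorbing (a missing fragment cannot
reappear, so IV → I transitions can only arise from hypermethylated loci
demethylating).

**Designing kernels.** `make_kernel(d, m, prior)` builds a kernel whose
expected demethylation/methylation rates over *classified* loci equal the
targets. Mass is spread over the 11 labeled transitions proportionally to
the empirical weights, but a source state can never emit more transition
mass than its prior frequency: over-subscribed states are capped and the
excess is redistributed within the category, with an error when total
capacity runs out — you cannot demethylate loci that carry no methylation.
The solver also handles the feedback between the rates' denominator and the
kernel itself (loci that start hypermethylated and do not move are IV → IV,
hence excluded). Exactness is unit-tested via `kernel_rates()` to 1e-9,
including redistribution cases. The parameter-recovery grid (d up to 0.2)
is run under a methylation-rich prior for exactly this feasibility reason.

**Recovery.** `recover_rates()` is the method-of-moments inverse: class-B
and class-C fractions estimate d and m, with binomial standard errors.
Acceptance: over 20 fixed seeds at 10 000 loci under d = 0.0905,
m = 0.0367, the mean estimates fall within 3 binomial SEs of the targets.

## Relative expression (2^−ΔΔCt)

`relative_expression()` is the plain 2^−ΔΔCt rule — no
amplification-efficiency correction. `summarize_replicates()` averages
technical replicates per biological sample, takes the control baseline as
the mean control ΔCt, and computes a fold change *per biological replicate*
before reporting mean ± SD per condition: the published fold-change figures
show per-replicate error bars, which the alternative (average Ct first,
exponentiate once) cannot produce. Consequences of this choice: the control
condition's geometric mean fold is exactly 1 (the arithmetic mean is 1 only
without noise), and fold changes are invariant to any global Ct shift
(property-tested).

## Numerical and degenerate-input policy

* Percentages: unrounded internally; `round_half_up(…, 2)` at reporting.
* Zero denominators error loudly (`no scorable loci`,
  `no classifiable loci`) rather than yielding NaN.
* Band cells outside {0, 1, NA} are validation errors naming the locus and
  sample; missing cells are excluded pairwise and logged.
* Empty sequences digest to empty fragment sets; motif windows containing
  `N` never match.
* Seeds are mandatory for every stochastic operation; the RNG state of the
  caller is saved and restored.

## Known limitations

* Sites are independent: no spatial correlation, no CHH/CHG context, no
  dose–response structure in the kernel.
* No PCR efficiency, adapter chemistry, or band-intensity modelling;
  selective-base primer filtering is not modelled (the source protocol's
  primer extensions are not available), so simulated band counts per gel are
  not calibrated to any real primer panel.
* `gel_mode` models comigration only as exact length collapse — no sizing
  error.
* Group comparisons are descriptive; the assay's standard tables carry no
  hypothesis tests, and none are provided.
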