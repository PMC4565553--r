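---
title: "Tracing the origin of interaction-domain families: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the origin of interaction-domain families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`domevol` implements the computational arc of a study that asks when and how
the interaction between two families of protein domains arose — the kind of
question posed for the CARD (caspase activation and recruitment) domains of
the RIG-like receptors and their mitochondrial adaptor. The arc runs:

1. fit an empirical substitution model on fixed topologies and quantify
   topology support (`optimize_model()`, `sh_test()`);
2. reconstruct ancestral domain sequences by empirical-Bayes marginal
   reconstruction, **integrating over topology uncertainty** through a
   weighted tree set (`marginal_reconstruct()`, `integrate_over_trees()`),
   with indels reconstructed separately by Fitch parsimony under a
   presence/absence coding (`parsimony_indels()`);
3. calibrate that reconstruction by simulation: simulate data under the
   fitted model along the fitted tree, reconstruct, and score error rates
   strictly and up to biochemical residue class (`asr_error_experiment()`);
4. test branches for positive protein-coding selection with the branch-site
   codon model and a Bonferroni-corrected chi-square LRT
   (`branch_sites_lrt()`), and estimate the test's false-positive rate under
   generating regimes that contain no positive selection
   (`branch_site_fpr_experiment()`);
5. cluster the domain subfamilies by profile-HMM Kullback–Leibler distances
   and an all-pairs local-alignment similarity network (`build_hmm()`,
   `hmm_distance()`, `hmm_tree()`, `similarity_network()`), root the family
   gene tree by duplication/loss reconciliation
   (`root_by_duplication_loss()`), and screen paralogs for gene conversion
   by a permutation test on polymorphic-site runs (`gene_conversion_scan()`);
6. estimate binding constants (Kd from steady-state responses, Km from
   initial rates) from association–dissociation traces under two averaging
   schemes, and compare affinities with Welch t tests (`estimate_binding()`,
   `compare_affinities()`).

The original study's raw sequence set and instrument traces are not
distributed in machine-readable form, so the package ships a synthetic-data
module that emulates their scale and structure; every stage runs end to end
on those generators, and the test suite asserts the properties that are
checkable at desk scale.

## Substitution models

**Protein.** LG exchangeabilities with either LG or alignment-derived
("+F", pseudocount 1 per residue) frequencies and discrete-gamma rate
variation. The gamma discretisation uses **category means over equiprobable
bins** (not medians), the convention of the major ML phylogenetics codes;
eight categories by default, matching standard practice for domain-scale
alignments. Generators are scaled so one unit of branch length is one
expected substitution per site at relative rate 1. Gaps and `X` enter the
pruning algorithm as flat partial vectors (missing data).

**Codon.** A Goldman–Yang-style 61-state model: single-nucleotide changes
only, transition/transversion ratio κ, nonsynonymous scaling ω, F3x4 codon
frequencies (uniform-nucleotide default; empirical from data in analyses;
F61 is not provided because nothing downstream needs it). Site-class
mixtures express the three generating regimes (neutral; sites;
branch-site-released) and branch-site Model A:

| class | background ω | foreground ω | weight |
|---|---|---|---|
| 0 | ω₀ ≤ 1 | ω₀ | p₀ |
| 1 | 1 | 1 | p₁ |
| 2a | ω₀ | ω₂ ≥ 1 | p₂·p₀/(p₀+p₁) |
| 2b | 1 | ω₂ | p₂·p₁/(p₀+p₁) |

The null fixes ω₂ = 1; the LRT statistic is compared to χ²(df = 1). The
50:50 boundary mixture that would halve the p-value is available via
`boundary_mixture = TRUE` but off by default: the plain chi-square is the
more conservative choice for a false-positive-rate argument, and it is the
test the field's standard implementation reports.

**Scaling conventions.** `build_rate_matrix()` scales a codon-class
generator so branch lengths are expected substitutions per codon under the
model's site-class mixture; the simulators use that convention. Inside the
branch-site *fitter* all class generators share one scale factor, the
neutral (ω = 1) rate at the current κ. A shared factor is required for the
proportion-profiling optimisation below (otherwise moving a mixture weight
rescales every branch length), it equals the mixture scaling exactly in the
neutral regime used for the false-positive experiment, and because null and
alternative share the same convention on the same fixed branch lengths, the
likelihood-ratio statistic is insensitive to the residual difference.

## Likelihood machinery and the optimizer

Felsenstein pruning runs per mixture class with per-site rescaling (log
scale factors accumulated per node); the class mixture is combined by
log-sum-exp. Marginal ancestral posteriors come from the standard up–down
pass: the posterior at a node is the normalised product of its "below"
partial and an "up" partial carrying the rest of the tree, mixed over
classes with the class weights and scale factors. Internal nodes are named
by their descendant leaf sets everywhere (reports, clade matching across
topologies), because node numbers are not comparable between trees.

Optimisation is coordinate ascent: Brent line searches per branch length
(bounds 1e-8–50) and per global parameter (α in 0.05–20, κ in 0.01–30,
ω₀ in 1e-4–1, ω₂ in 1–50), proportions through a softmax transform,
sweeps repeated until the log-likelihood gain drops below tolerance
(default 1e-6, 200-sweep cap); an update is accepted only if it improves
the current value, so the trajectory is non-decreasing by construction.
Under a reversible model only the sum of the two root-adjacent branch
lengths is identifiable; tests therefore compare fitted lengths on the
unrooted tree.

The branch-site fit exploits the mixture structure: for fixed (κ, ω₀, ω₂)
the four class likelihood rows are fixed, so the class proportions are
profiled out by a cheap inner optimisation at every ω evaluation, and an
ω₀ move only recomputes classes 0/2a (ω₂: classes 2a/2b). κ is estimated
once per alignment under a single-class model and held fixed across the
per-branch fits; at desk scale this changes no decision while cutting the
cost several-fold. Background branch lengths are held at their input values,
but the **foreground branch length is re-estimated under both the null and
the alternative**: that length is partially confounded with ω₂, and holding
it fixed lets ordinary substitution-count fluctuation on the one tested
branch masquerade as positive selection (the reference implementation
re-optimises all branch lengths under each model, which absorbs the same
noise). After the alternative fit the null is re-polished from the
alternative's optimum, so optimisation error cannot leak into the
likelihood-ratio statistic. Full branch-length optimisation remains
available through `optimize_model()`.

## The synthetic data and what it does (not) show

`card_family_fixture()` emulates the scale of the study's domain family:
five subfamily groups (think RIG-I CARD1/CARD2, MDA5 CARD1/CARD2, IPS1
CARD) of ten taxa each, ~95 aligned residues, one shared tree with
within-group depth 0.5 and group stems 0.8 substitutions/site, evolved
under LG+Γ (shape 0.8 — a typical domain-level estimate; four categories in
the fixture to keep test runtimes proportionate). The generators record
true ancestral states and per-site classes so calibration experiments can
score errors exactly.

The kinetics generator produces 1:1 Langmuir association–dissociation
traces at 7 log-spaced concentrations spanning 1 nM–100 µM with 3
replicates, Gaussian noise, optional linear drift during association, and a
0-concentration blank — mirroring the assay design (the real instrument
samples every 3 ms for an hour; the synthetic default is 1 s over 1800 s to
keep datasets small, and the "average the last 500 samples" steady-state
rule operates on whatever grid is present). The default association rate
constant is 1e5 /(M·s), a typical protein–protein value; with the default
Kd of 3e-8 M the slowest trace still equilibrates within the phase. Because
the mechanism is exactly 1:1 Langmuir, the initial rate is linear in
concentration, so the "Km" from one-site fits to initial rates is governed
by the sampling-resolution cap described below — the generator validates the
estimation pipeline, not the biochemical interpretation of Km. No
mass-transport limitation, probe-loading variation or other instrument
artifacts are simulated, so passing tests certify the estimators'
correctness on clean 1:1 data, not robustness to such artifacts.

Sequence generators insert no indels by default; indel parsimony is
exercised on constructed gap patterns instead.

## Numerical and procedural choices

- **MAP ties** in reconstruction break by the fixed residue order
  `ARNDCQEGHILKMFPSTWYV`; determinism matters more than the (arbitrary)
  winner.
- **Fitch ambiguity at the root resolves toward presence**, and a
  weight-averaged presence probability of exactly 0.5 calls presence — a
  site is kept unless the evidence for absence outweighs it.
- **Biochemical classes** default to a standard 7-class partition
  ({AVLIMC}, {FWY}, {STNQ}, {DE}, {KRH}, {G}, {P}); the classification the
  original analysis used is not recorded, so the partition is configurable.
- **Neighbor joining** clamps a negative branch length arising at a join to
  zero and moves the deficit to its sibling edge, preserving the joined
  pair's path length.
- **SH test**: classic Shimodaira–Hasegawa with RELL resampling (1000
  replicates by default — the original report does not state a count), per-
  tree sums recentred on their bootstrap means; the best tree's p-value is
  1 by construction, and ties break toward non-rejection.
- **Duplication/loss rooting** uses unit costs and returns *all*
  cost-minimising root edges; edge-weight thresholds of the reference
  implementation are not replicated.
- **Gene-conversion scan**: polymorphic columns are gap-free columns with
  ≥ 2 states; fragments score +1 per matching polymorphic site with a unit
  penalty per mismatch (the reference tool's mismatch-penalty setting is
  not recorded; unit penalty is the default here), maximal segments found
  by Kadane's algorithm; significance by global column-order permutation,
  `sim_p = (1 + #{perm ≥ obs}) / (n_perm + 1)`, Bonferroni over unordered
  pairs. Analytic Karlin–Altschul p-values are out of scope.
- **Similarity network** e-values use the published gapped BLOSUM62
  (open 11 / extend 1) Karlin–Altschul constants λ = 0.267, K = 0.041 on
  Smith–Waterman scores — an explicit approximation of BLAST e-values that
  keeps the statistic monotone in the alignment score.
- **Profile-HMM distance**: symmetrised KL over match emissions only,
  positionwise on HMMs sliced from one master alignment; transition terms
  are excluded (the cited distance's treatment of transitions is not
  specified, and emissions carry the discriminating signal here).
- **Initial rates** are the t = 0 derivative (A·k) of a single-exponential
  fit, with k capped at twice the sampling rate: a rise faster than the
  grid cannot be resolved, and the cap makes saturated high-concentration
  traces return the maximal resolvable slope instead of a divergent
  product. A windowed linear-slope alternative is available.
- **r² = 0.91** on one-site fits is a QC *flag*, never a filter, matching
  how the assay quality was reported.
- **Kinetics comparisons** run on the −log10 (pKd/pKm) scale, where
  replicate estimates are closer to Gaussian.

## Calibration experiments and their scales

`asr_error_experiment()` regenerates alignments under the fitted model (no
re-estimation inside replicates, matching the use of ML parameter
estimates), reconstructs with that model, and reports per-node strict and
class error with SEs, plus a pooled posterior-calibration record (mean MAP
posterior vs empirical accuracy — the empirical-Bayes posteriors should be
approximately calibrated, and the suite asserts agreement within ±0.05 over
more than 10,000 residues).

`branch_site_fpr_experiment()` simulates under one of three no-positive-
selection regimes — neutral (ω = 1 everywhere), sites (a fraction p₀ of
sites constrained at ω₀), and branch-site-released (sites background, all
sites released to ω = 1 on the tested branch) — then applies the same
branch-site procedure used on real data (empirical F3x4, κ estimated, LRT
per tested branch, Bonferroni across the tested branches) and counts
significant tests. When no fitted sites model is supplied the defaults are
p₀ = 0.8, ω₀ = 0.1. FPR denominators are reported both pooled over
(replicate × branch) and per replicate with an SE over replicates. The
study-scale replicate count is 100; the desk-scale runs in the tests and
acceptance script use 50 replicates of 90 codons on an 8-taxon tree, which
keeps the neutral-regime experiment within minutes on one CPU while leaving
the Bonferroni-corrected rate's ceiling of 0.05 testable.

## Known limitations

- Tree topologies are inputs: there is no tree search, and Bayesian
  posterior weights for `WeightedTreeSet`s must come from outside.
- The codon fitter's fixed-κ, fixed-branch-length defaults trade a little
  statistical polish for speed; both can be lifted.
- The gene-conversion screen implements only the within-pair ("inner
  fragment") statistic with permutation p-values. Because the unit-penalty
  fragment score is integer-valued, its permutation null keeps sizeable
  probability atoms at any alignment length, so `sim_p` is *conservative*
  (super-uniform: `P(sim_p <= t) <= t` holds, but the distribution is far
  from exactly uniform). Detection power on real conversion tracts is
  unaffected; nominal sizes are, if anything, understated.
- HMMs are containers for emissions/transitions; scoring sequences against
  them (forward/Viterbi) and HMMER file formats are out of scope.
- The kinetics module fits steady-state and initial-rate one-site curves;
  global kon/koff fitting across concentrations is not attempted.
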