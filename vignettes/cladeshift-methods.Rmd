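---
title: "Models and methods behind cladeshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cladeshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cladeshift)
```

cladeshift is a pipeline for asking how the molecular evolution of a gene
family differs between two plant clades — grasses (Poaceae) and eudicots —
from ortholog-group construction through duplication/loss inference, dN/dS
comparison, positive-selection scanning, and type-II functional divergence.
This vignette explains the models and the choices behind each stage: what is
estimated, under which assumptions, which knobs matter, and where the
boundaries of the approach lie. Everything quantitative stated here is
computed by the package's test suite or by `scripts/acceptance.R`; nothing is
quoted from elsewhere.

## The synthetic-data generator

Real analyses of this kind consume a dozen sequenced genomes. To make every
stage verifiable without downloads, `simulate_family()` generates a complete
two-clade gene family together with a truth log:

* A species tree whose root bipartition separates the grass leaves from the
  eudicot leaves (`simulate_species_tree()`). Topologies within a clade are
  random; every branch length is drawn uniformly from
  `branch_length_range`, in units of expected substitutions per codon site.
  The default range `c(0.05, 0.3)` puts typical tip-to-tip divergences in
  the regime where distance methods are informative but not saturated.
* Codon sequences evolved along the gene tree under the Goldman–Yang (GY94)
  codon model over the 61 sense codons: single-nucleotide codon changes are
  rated by the transition/transversion ratio κ, the nonsynonymous/synonymous
  ratio ω, and target-codon frequencies π. The generator of each regime is
  rescaled so that one unit of branch length is one expected substitution
  per codon site at stationarity, which makes simulated branch lengths
  directly comparable to fitted ones. Rates into stop codons are zero by
  construction.
* Injected events. An *old duplication* sits on a clade's stem, so every
  species of that clade inherits the extra subfamily; k stem duplications
  yield k+1 clade-wide subfamilies. A *recent duplication* splits one
  species' terminal branch at its midpoint, giving that species a second
  copy within the same subfamily. A *recent loss* prunes one single-copy
  gene. Losses deliberately avoid slots touched by a recent duplication so
  that the per-species copy-number ledger
  (copies = 1 + old dups of the clade + recent dups of the species − losses
  of the species) stays exactly checkable.
* Determinism. One seed governs everything. Sequence evolution uses one
  substream per branch, keyed by the sorted leaf set below that branch, so
  unrelated parts of the tree do not share randomness.

What the generator does *not* emulate: indels (alignments are gap-free true
homologies), codon-usage mutation bias, rate variation across sites outside
the explicit site-class mode, and lineage sorting. Tests passing on these
simulations therefore validate the estimators under their own model
assumptions; they say nothing about alignment error or model violation in
real data.

For site-model experiments, `site_classes` assigns each codon site a fixed ω
drawn from configured class proportions. All classes share one branch-length
scale (the mixture-average rate), so sites under positive selection evolve
faster in absolute terms, exactly as in the likelihood model below. An
earlier draft normalized each class separately; that erases the rate signal
that distinguishes fast sites and roughly halves empirical-Bayes detection
power, which is why the shared scale is load-bearing.

## Ortholog groups from similarity tables

`cogs_from_hits()` follows the classical cluster-of-orthologous-groups
recipe on a 12-column tab-separated hit table (BLAST `outfmt 6` dialect):

1. *In-paralog collapse.* Two same-species genes collapse when their mutual
   bitscore exceeds both genes' best inter-species bitscores; clusters are
   the transitive closure, represented by the longest member (self-hit
   alignment length; ties break lexicographically).
2. *Best hits (BeTs).* For each gene and each other species, the single
   highest-bitscore subject; ties break by smaller e-value, then gene id.
   Bitscore-then-e-value is used because bitscores are length-normalized
   and comparable across queries.
3. *Symmetric BeTs* are reciprocal best hits.
4. *COGs.* Seeds are triangles of symmetric BeTs spanning three species;
   triangles sharing an edge merge transitively. Genes in no triangle stay
   unassigned.

The merge is validated in the test suite against brute-force triangle
enumeration plus union on random graphs.

## Gene trees and subfamilies

Trees are built by neighbor joining on protein p-distances with pairwise
deletion, the distance-based branch of the usual two-method (NJ + ML)
analysis; maximum-likelihood reconstruction is intentionally not
reimplemented, since on these families the two methods give the same
topologies and every downstream stage consumes only the topology and
support values. The in-package NJ exists (rather than wrapping an external
one) because the pipeline's contract fixes two details most implementations
leave unspecified: Q-matrix ties break on the lowest index pair, and
negative estimated branch lengths are clamped to zero with the deficit
moved to the sibling so path lengths are preserved. The implementation is
cross-checked against the reference NJ in `ape` and must reproduce additive
trees exactly.

Bootstrap support resamples alignment columns with replacement and scores
each internal bipartition of the full-data tree by its replicate frequency.
An alignment of identical sequences is declared `unresolved` with all
supports zero rather than an error.

`partition_subfamilies()` roots the tree on the branch whose bipartition
best separates the clades (ties prefer the longer branch) and then cuts it
into *subfamilies*: maximal clade-pure clades with support at or above
`min_support` (default 50, matching the convention of displaying only
supports above 50%). One refinement is essential: a clade-pure node is
split further when it is a duplication node — both children span at least
two species and their species sets overlap. Without this species-overlap
criterion a stem duplication would merge its two subfamilies into one pure
clade and become invisible; with it, k stem duplications yield exactly k+1
subfamilies. Orthology between clades is formalized as most-recent common
ancestry: each subfamily pairs with the opposite-clade subfamily(ies) whose
MRCA with it is deepest.

## Duplication and loss calls

From subfamily structure, `classify_duplications()` scores k−1 old
duplications for a clade with k subfamilies (a binary-duplication parsimony
count) and m−1 recent duplications for a species with m members in one
subfamily. `classify_losses()` scores a recent loss for every roster
species missing from a subfamily — the roster is supplied explicitly,
because a species that lost its only copy is invisible in the data — and an
old loss for the opposite clade when a subfamily's orthology pairing is
non-mutual (the pattern left when an entire clade lacks an orthologous
subclade). A duplication predating the clade split leaves k ≥ 2 subfamilies
in *both* clades and is counted as an old duplication in each, which is the
closest rule-based reading of "old" when both clades retain both copies.
Losses are reported as inferred; no external database re-validation is
attempted. The classifier composed with the simulator recovers injected
event counts exactly on desk-scale families — the inference is
deterministic given a correct tree, so this is an all-or-nothing check of
the rules, not a statistical one.

## Pairwise dN/dS and the clade comparison

`ng86()` implements Nei–Gojobori counting: fractional synonymous and
nonsynonymous site counts per codon (stop-codon targets excluded from the
per-position fractions, so S + N = 3 per codon exactly), equal-weight
averaging over all minimal mutational pathways between differing codons
(stop-passing pathways excluded), and the Jukes–Cantor correction
d = −(3/4)·log(1 − 4p/3). The correction is undefined at p ≥ 3/4 and the
estimate is then flagged invalid rather than clamped. NG86 assumes no
transition/transversion bias; under κ > 1 it is biased downward for ω (the
classical behaviour), so its consistency test runs at κ = 1 where the
estimator matches its own model. A pairwise maximum-likelihood ω
(`ml_pair_omega()`, a one-branch GY94 fit) is provided behind the same
contract and used for cross-method concordance, never mixed with NG86
values in one analysis.

`sample_pair_omegas()` draws distinct within-subfamily pairs uniformly
without replacement (default 20 per subfamily — enough to stabilize the
subfamily mean without resampling the same information many times over) and
`compare_clades()` applies the paired t-test to index-paired grass and
eudicot samples: the i-th grass pair matches the i-th eudicot pair of the
orthologous partner subfamily, a pairing made explicit in the output
because the choice is otherwise arbitrary. Pairs with an invalid ω are
dropped together with their partner. Zero-variance nonzero-mean differences
are reported significant with a below-machine-floor p-value and a
`degenerate` flag, rather than producing NaN. Raw p-values are reported at
α = 0.05 with no multiple-testing correction, and this is deliberate: the
verdict column mirrors the single-family decision rule, and readers who
need family-wise control can apply `p.adjust` to the output table.

## Likelihood machinery and codon models

`codon_loglik()` runs Felsenstein pruning over the 61 sense codons with
per-pattern numerical rescaling, site-pattern compression, and gap codons
as missing data (all-ones partial vectors). Equilibrium frequencies default
to F3×4 — position-specific nucleotide frequencies multiplied and
renormalized over sense codons. Transition probabilities come from the
symmetric eigendecomposition available for reversible generators; the
pruning kernel is compiled (RcppArmadillo) because model fitting evaluates
the likelihood thousands of times. The pruning route is tested to 1e-8
against exhaustive summation over all internal-state assignments on tiny
trees, and for invariance under rerooting (the pulley principle).

`fit_codon_model()` fits three flavours by maximum likelihood:

* **M0** — one ω for the whole tree;
* **BRANCH2** — ω_grass and ω_eudicot, each branch taking the clade of its
  descendant leaves (the two root-adjacent branches take their subtree's
  clade);
* **M3K3** — a three-class discrete site model with free class proportions
  (softmax-parameterized) and ordered ω estimates.

Optimization alternates a substitution-parameter block with a
branch-length block, both log-transformed under L-BFGS-B, until the
relative log-likelihood gain falls below 1e-8; eigendecompositions are
cached across the branch-length block. ω is bounded in [1e-4, 20] — the
upper bound is where boundary estimates park when a class is effectively
unconstrained — with `bound_hit` flags reported honestly. The first start
is deterministic (richer models start from an M0 fit, which also guarantees
the nested-model inequality lnL_alt ≥ lnL_null at the starting point);
seeded random restarts are available via `n_starts` but are off by default,
because on these unimodal likelihoods they never changed the optimum in
testing and only multiply the runtime. Identical-sequence alignments drive
branch lengths to the lower bound and leave ω effectively unidentified —
the fit returns finite lnL and flags rather than erroring.

`lrt()` uses the 2·|ΔlnL| convention so it applies equally to fitted
objects and to pairs of printed −lnL values, with an upper-tail chi-square
p-value. The degrees of freedom are an explicit argument. Asymptotically
the two-ratio branch model adds a single ω parameter (χ²(1)); the
package's null-calibration experiment (200 replicates at 3+3 taxa × 150
codons) finds the empirical statistic slightly heavier-tailed than χ²(1)
at that size — rejection near 8–9% at the χ²(1) quantile and 2–3% at the
χ²(2) quantile — so at desk scale the distribution sits between the two
references. Published branch-test tables in this literature are
numerically consistent with df = 2, and the report layer defaults to
df = 2 while the test decision remains the caller's. P-values below 1e-12
are printed as `<1.00e-12` in report tables.

`neb_sites()` performs naive empirical Bayes on a fitted M3 model:
per-site class posteriors proportional to class proportion times class
site-likelihood, sites reported when their posterior mass on classes with
ω > 1 reaches the threshold (default 0.95). The site-recovery experiment
(10 taxa, 500 codons, 10% of sites at ω = 3 against a 0.2 background,
branch lengths 0.1–0.3) reflects deep two-clade families where total tree
length is several substitutions per site; at that depth the posterior
threshold of 0.95 yields sensitivity well above one-half at essentially
zero false positives. Bayesian (BEB) site inference and switching models
are out of scope.

## Type-II functional divergence

`estimate_theta2()` is a moment estimator of the type-II divergence
coefficient between two subfamily clusters sharing one master alignment.
Columns with more than half gaps in either cluster are excluded; the rest
are classified as conserved-in-both-and-same, conserved-in-both-but-
different (the type-II pattern), or variable. With F_obs the fraction of
dually-conserved columns fixed for different residues, and F_exp the
p-distance between the two cluster consensus sequences (majority residue
per column — a proxy for the cluster ancestors) passed through the Poisson
correction,

θ_II = (F_obs − F_exp) / (1 − F_exp),

with a binomial standard error propagated through the ratio and a
one-sided z-test against zero. Conditioning F_exp on the consensus rather
than on mean pairwise distance is what gives the estimator its power:
pairwise distances include within-cluster tip variation, which inflates
the expectation until no excess of fixed differences can ever register,
whereas consensus distance isolates the between-cluster component. Under
neutral simulation the estimator centres on zero; under cluster-specific
fixed shifts at 30% of sites it rejects in ≥80% of replicates while
no-shift controls stay below the 10% line — the contrast expected between
non-orthologous (post-duplication) and orthologous cluster pairs. This is
deliberately *not* a reimplementation of DIVERGE's internal likelihood;
it preserves the reported contract (θ ± SE, significance against zero)
with a fully specified, testable statistic. All cluster members enter
unweighted.

## Pipeline, determinism, and problem sizes

`run_pipeline()` chains the stages with one root seed split
deterministically per stage, writes each report table as TSV (floats at 6
significant digits; p-values in scientific notation with the `<1.00e-12`
floor), and emits a manifest with a config hash so that byte-identical
outputs certify a faithful re-run. Stage failures abort with the stage
named, keeping earlier outputs on disk.

The validation experiments are sized to run on one CPU in minutes, and the
same sizes are used by the acceptance script: 20 replicates at 5+5 taxa ×
300 codons for branch-model recovery; 200 replicates at 3+3 taxa × 150
codons for the null LRT calibration; one 10-taxon × 500-codon family for
site detection; 50 replicates each for the NG86 consistency and θ-II
contrast experiments. These sizes were chosen as the smallest at which the
statistical criteria are comfortably identifiable, and they are part of
the package's documented study conditions.

## Known limitations

* The simulator's gap-free alignments mean alignment uncertainty is
  untested; real use should start from curated alignments.
* Subfamily partition depends on a correct tree; at very low divergence or
  heavy loss the species-overlap rule can miss a stem duplication whose
  surviving children span fewer than two species.
* NG86 ω inherits the estimator's downward bias under transition bias;
  use the ML pairwise route when κ is far from 1.
* The branch model assumes clade-constant ω; lineage-specific episodes
  inside a clade are averaged away.
* θ-II consensus distances assume clusters are individually well
  conserved; for highly diverged clusters (consensus distance approaching
  saturation) the Poisson correction becomes unstable and the estimate is
  flagged rather than trusted.
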