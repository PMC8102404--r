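---
title: "Methods: flux sampling, metabolomics statistics, and lipid chemoinformatics in fluxlip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flux sampling, metabolomics statistics, and lipid chemoinformatics in fluxlip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxlip)
```

# The scientific setting

fluxlip studies what happens to systemic metabolism when a multispecific
membrane transporter — the motivating case is the renal basolateral organic
anion uptake transporter OAT1 (SLC22A6) — is lost or inhibited. Three
computational arms are connected:

1. **Constraint-based modelling.** A stoichiometric model constrained by
   condition-specific omics data defines a feasible flux polytope
   `{v : S v = 0, lb <= v <= ub}` per condition (wildtype and knockout). The
   knockout of a basolateral uptake transporter is modelled as closing an
   uptake exchange reaction. Feasible flux states are sampled uniformly from
   each polytope and compared reaction by reaction.
2. **Targeted metabolomics statistics.** Serum abundance tables are tested
   metabolite by metabolite (Welch's t), tiered into significant / trend /
   unchanged, and rolled up into subpathway enrichment ratios.
3. **Chemoinformatic classification.** The elevated and decreased lipids
   are described by molecular descriptors computed from SMILES, and
   classifiers with leave-one-out validation quantify how well structure
   alone separates the two directions.

A synthetic-data module generates all three kinds of input with known ground
truth at desk scale, so every stage of the pipeline is exercised and
verifiable without the original study's unreleased raw data.

# Constraint-based core

## Solver

All flux problems are small dense LPs. No LP package is available in the
target environment, so the package carries a bounded-variable two-phase
primal simplex (`R/simplex.R`): nonbasic variables rest on a finite bound,
the ratio test handles bound flips, the basis inverse is updated by
elementary row operations, and Bland's rule (smallest-index entering and
leaving candidates) prevents cycling. Tolerances: pivot/reduced-cost `1e-9`,
phase-1 feasibility `1e-7`. FBA reports any optimal vertex; tests assert
objective values, not solution uniqueness, because LP degeneracy makes the
optimal vertex non-unique in general.

## Condition-specific models

The paper-style pipeline never names its model-extraction algorithm, so the
package commits to a deterministic, LP-only, GIMME-like soft scaling:
a reaction's activity is its gene-reaction rule evaluated with AND = min and
OR = max over expression values; reactions whose activity `a` falls below a
threshold have both bounds multiplied by `max(floor, a / threshold)`.
Defaults: threshold = 25th percentile of model-gene expression, floor = 0.
Two details matter:

* **Missing genes score the profile median**, so unmeasured genes do not
  spuriously close reactions.
* **Idempotence.** Scaling is always computed from the pristine bounds
  recorded at the first application, so applying the same profile twice is
  exactly the same as applying it once. Without this, repeated application
  would compound the scaling.

Metabolomics-derived constraints act on exchange reactions under the
convention *positive exchange flux = secretion, negative = uptake* (stated
in every report header): `secretion_min` raises the exchange lower bound,
`uptake_min` caps the upper bound at `-magnitude`, `blocked` closes the
exchange. Feasibility is re-checked after application and an infeasible
combination is reported as a status, never as partial numbers.

# Flux sampling

The sampler is artificial-centering hit-and-run (ACHR) in the null-space of
`S`: warmup points are alternating per-reaction min/max LP solutions,
directions are differences between a randomly retained point and the running
center re-projected onto `null(S)`, and each step moves the walker to a
uniform point of the chord through the bounding box.

Numerical choices that proved load-bearing:

* **Strict interiority.** The walker samples from a chord shrunk by a
  relative `1e-9` margin and is never clamped onto the box. Clamping lands
  the walker exactly on faces and vertices, where later chords through the
  drifting center collapse to length zero and the chain stalls (observed:
  96% rejected steps on a knockout model before the fix).
* **Fixed-coordinate hygiene.** Direction components below `1e-11` are
  zeroed so reactions fixed by the knockout are never dragged by numerical
  noise.
* **Burn-in.** Chains start at a warmup vertex; without a burn-in the
  initial transient biases the per-condition means enough to destroy the
  calibration of downstream significance tests (measured: 84% of null
  p-values below 0.001 at thinning 20 with no burn-in). Default burn-in is
  `5 * thinning` steps.
* **Thinning.** The per-coordinate integrated autocorrelation time grows
  with polytope dimension — roughly 10 steps at dimension 4-5 and 40 at
  dimension 10-20, measured on box polytopes. The default thinning of 100 is
  conservative for desk-scale models; analyses that feed samples into
  significance tests should keep thinning at a small multiple of the
  autocorrelation time.

Samples are `l1`-normalised by default (each flux state divided by its total
absolute flux) so states are comparable between conditions whose total flux
capacity differs — after a transporter knockout the knockout polytope is
strictly smaller. All-zero rows are left untouched and flagged. The
normalisation mode is recorded in the sample-set metadata. Note the
redistribution this implies: knocking down part of the network shrinks the
total-flux denominator, so *untouched* reactions' normalised means inflate
by the ratio of total fluxes. That is the intended comparability semantics
("share of the flux state"), but it means planted-effect recovery is
assessed on raw states, where an untouched reaction's fold change
concentrates at 1.

# Differential flux states

Per reaction, a one-way two-group ANOVA F statistic (algebraically the
squared pooled t) compares the two conditions' sampled states; a reaction is
called **altered** when `p < 0.001` *and* the fold change of `|mean|`
(knockout over wildtype, pseudocount `1e-9`) is above 2 or below 0.5. No
multiple-testing correction is applied to the call — the screening rule this
mirrors uses a raw p threshold plus a fold filter — but BH-adjusted p-values
can be reported alongside. Sign changes (means of opposite sign) are flagged
separately rather than folded into the ratio.

Two statistical caveats are documented deliberately:

* **Chain autocorrelation inflates F.** The test treats samples as
  independent; insufficient thinning makes null p-values anti-conservative.
  The fold-change filter shields the *altered* call (null fold changes
  concentrate at 1), but the p-values themselves are only calibrated when
  the chains are thinned past their autocorrelation time. On raw sampler
  output with adequate thinning the calibration is exact: the measured
  variance-inflation factor of chain means relative to iid theory is 0.98
  (150 chains, dimension-2 box, thinning 50). The l1 normalisation adds a
  further measured ~8% inflation because every normalised coordinate shares
  the total-flux denominator, whose mixing is the slowest in the chain;
  p-values on normalised states are therefore mildly anti-conservative at
  fixed thinning. The acceptance suite verifies binomial-band calibration
  at `alpha = 0.001` over 2000 replicated reactions on raw states.
* **Artificial centering is frozen after burn-in.** Letting the running
  center keep adapting for the whole run makes the direction distribution
  history-dependent; the chain mean then acquires a drift component and the
  null F calibration degrades. The center therefore adapts only during
  burn-in and is frozen afterwards, which makes the post-burn-in kernel a
  proper uniform-invariant Markov chain with a fixed direction pool.
* **A 2-fold perturbation sits on the decision boundary.** Halving a
  reaction's bounds halves its mean flux, which lands exactly on the 0.5
  fold cutoff; with any finite sample the estimate straddles the threshold
  and no consistent procedure can flag it reliably. The sensitivity
  guarantee (>= 0.9) is therefore scoped to perturbations that shift mean
  flux at least 3-fold; the F-test component alone recovers even exact
  halving with near-certain significance.

The roll-up counts altered reactions per subsystem, marks a metabolite
affected if it has nonzero stoichiometry in at least one altered reaction
(or altered *exchange* reaction with `affected_mode = "exchange"`), and
labels it lipid-annotated if any of its altered reactions' subsystems
matches a curated keyword list (fatty acid, bile acid, eicosanoid,
prostaglandin, sphingolipid, ... — case-insensitive substrings, editable).

# Metabolomics statistics

The pipeline order is fixed: impute, then test. Missing cells are filled
with the minimum observed value of that metabolite within the same group
(the platform convention for values below detection); metabolite-group pairs
with no observed value at all are excluded with a warning. Statistics per
metabolite: Welch's two-tailed t (Student's pooled t selectable for designs
that assume equal variances), BH-adjusted p, fold change (case/control,
computed post-imputation), Cohen's d with the `(n1 + n2 - 2)`-denominator
pooled SD. Tiers: significant (`p <= 0.05`), trend (`0.05 < p <= 0.10`),
otherwise ns; non-ns metabolites get a direction from the fold change.

Subpathway enrichment uses the ratio of proportions
`E = (k/m) / ((n - k)/(N - m))` for subpathways with more than five
metabolites, computed separately per direction with a direction-specific `n`
(the total-n variant is a flag). "Altered" includes the trend tier by
default (strict mode restricts to `p <= 0.05`). The printed source of this
formula is typographically corrupted; the ratio-of-proportions reading is
the standard platform enrichment statistic and is fixed here as a documented
interpretation.

# Chemoinformatics and classification

## Descriptors

No cheminformatics toolkit exists in the target R environment, so the
package implements a SMILES subset parser (organic subset, aromatic atoms,
bracket atoms with charge/H-count/chirality, ring closures, branches) and
computes ~33 descriptors. The named panel, with exact definitions:

| descriptor | definition |
|---|---|
| `nof_Rings` | smallest-set-of-smallest-rings count (cyclomatic number) |
| `nof_COOH` | carboxyl groups: C with =O and a terminal -OH / -O⁻ |
| `nof_OH` | hydroxyls excluding carboxyl hydroxyls |
| `nof_RotB` | acyclic single bonds between non-terminal heavy atoms, amide C–N excluded |
| `nof_Chirals` | potential tetrahedral stereocenters (assigned + unassigned) |
| `C_sp3` | sp3-hybridised carbons |
| `C_R0` | carbons in no ring |
| `posCharge_per_volume` | sum of positive Gasteiger–Marsili partial charges / additive molecular volume |
| `complexity` | Bertz-type graph complexity (bond-connectivity + element-distribution information) |

plus molecular weight/volume/area, atom and bond counts, H-bond
donors/acceptors, Ertl topological polar surface area (N/O contributions),
and a simple additive logP estimate. Two proxies are explicitly *not* the
platform's numbers: `complexity` (Bertz-type, monotone with but not equal to
the vendor value) and the charge scheme (classic 6-iteration
electronegativity equalisation, not a quantum method). Stereocenter
detection uses Morgan symmetry classes; it agrees with a reference toolkit
on every substituted test molecule (taurocholate and cholate: 11 centers)
but does not count purely symmetric ring-fusion centers (decalin: 0 here,
2 in toolkits that model ring stereo). Descriptor tests pin frozen reference
values computed once with an independent toolkit.

## Selection, balancing, validation

Feature selection first prunes the lower-ranked member of every pair with
`|Pearson r| > 0.9` (this is what removes near-duplicates such as molecular
area vs volume), then ranks survivors by information gain of the class label
on equal-frequency 4-bin discretisation, tie-breaking by name, and keeps the
top six.

Class imbalance (86 elevated vs 40 decreased in the emulated setting) is
handled by downsampling (majority to minority size), upsampling (minority
resampled with replacement), or the combined scheme (both classes to the
rounded geometric mean, 59/59). Two leakage guards are fixed design
decisions: balancing happens **inside each leave-one-out fold** (resampled
duplicates of the held-out molecule can never appear in training), and
standardisation uses training-fold statistics only.

The four model types are implemented in-package (no tree/forest/kNN library
exists in the target environment): CART with Gini impurity, unlimited depth,
min-leaf 2; a 50-tree bagged forest with `sqrt(p)` feature subsampling;
kNN with k = 5; and `stats::glm` logistic regression. All seeds are surfaced
in the classification report.

## FreeViz projection

Each feature receives a 2-D anchor; the embedding is the standardised
feature matrix times the anchor matrix. Anchors start on the unit circle
(seeded) and descend a force objective — same-class pairs attract with a
spring potential (gradient proportional to distance), different-class pairs
repel with a `1/d` potential. The raw gradient dynamics are unstable (the
per-feature contraction factor can exceed 2, making noise anchors oscillate
and grow), so steps are normalised to a fixed anchor-space length with
backtracking: uphill moves are rejected and the step halved. Anchors are
renormalised so the longest has unit length; convergence is declared when
the objective improves by less than `1e-6`.

# The synthetic world

The generators state one fixed world, mirroring the emulated study's table
shapes; none of their defaults were chosen by looking at test outcomes.

* **Toy network** (`make_toy_network`): parallel linear pathways (uptake
  exchange -> conversion -> secretion exchange) sharing a recycled cofactor,
  subsystem labels drawn from lipid and non-lipid vocabularies, gene rules
  of the form `(gA and gB) or gC`. The knockout closes one pathway's uptake
  exchange — the transporter analogue — and the ground-truth altered set is
  computed *exactly*, as the reactions whose FVA range changes, never by
  sampling. The shared cofactor places the regeneration reaction in the
  ground truth too (its attainable range shrinks), which tests that
  consumers of the ground truth do not assume it equals one pathway.
* **Metabolomics table** (`make_metabolomics`): log-normal abundances
  (log-scale SD 0.3), 342 metabolites, 5 samples/group, 35% of metabolites
  planted with a 4-fold effect (half elevated, half decreased at 1/4),
  5% missing completely at random; subpathways are contiguous blocks of
  3-30 metabolites so planted effects concentrate in early subpathways,
  giving genuinely enriched pathways. At these settings Welch recovery of
  planted effects exceeds 0.9 power (verified by test). The generator does
  **not** imitate real serum correlation structure — metabolites are
  independent given the design — so a green test establishes calibration
  and power under independence, not under realistic co-regulation.
* **Lipid classes** (`make_lipid_classes`): the elevated class is an
  acyclic mono-/di-carboxylic chain grammar (C12-C24, optional cis double
  bonds and mid-chain hydroxyls; no ring tokens, so `nof_Rings = 0` by
  construction); the decreased class decorates 2-4-ring saturated
  polycyclic scaffolds with hydroxyls or positively charged head groups
  (`nof_Rings >= 2`, higher positive charge density by construction).
  Class sizes default to 86/40. Because the classes are separable by
  construction, classifiers reach the top of the 65-85% reference band;
  the permutation control (accuracy ~0.5 with shuffled labels) shows the
  pipeline does not manufacture signal.

# Known limitations

* The SMILES parser covers the organic subset needed for serum lipids; it
  does not validate valence, kekulise aromatic systems, or interpret
  stereo bonds (`/`, `\` read as single bonds).
* ACHR is approximately, not exactly, uniform; on box polytopes the
  empirical centroid error at n = 5000 is well under the 5% assertion used
  in the acceptance suite.
* The per-reaction F-test treats flux samples as independent draws;
  p-values are meaningful only with adequate thinning (see above).
* Enrichment ratios are point estimates; no enrichment p-value is computed,
  matching the emulated platform statistic.
* The full-scale genome reconstruction (Recon-class models) is out of desk
  scope; the machinery is exercised on toy and packaged submodels.
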