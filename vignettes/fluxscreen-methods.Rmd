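---
title: "Context-specific metabolic screening: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific metabolic screening: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscreen)
```

## The problem

Tumour cells rewire their metabolism, and some of those rewiring strategies
create dependencies a drug can exploit: knock out the right metabolic gene
and the tumour can no longer synthesise the precursors it needs to grow,
while healthy, non-proliferating tissue — which mostly needs to keep its
energy balance — is unharmed. `fluxscreen` implements this idea as a
computational screen. From a genome-scale metabolic reconstruction and
RNA-seq-style expression data it builds flux-consistent, context-specific
metabolic models of tumour samples and of healthy controls, simulates the
deletion of every gene and of every drug's full target set, and ranks
drugs by how selectively they abolish tumour growth.

## Model and procedure

### Flux balance analysis

A metabolic network with stoichiometric matrix $S$ is assumed to operate at
steady state, $S v = 0$, with each reaction flux $v_i$ confined to bounds
$l_i \le v_i \le u_i$ (mmol/gDW/h). Flux balance analysis (FBA) maximises
the flux through an objective reaction under these constraints — a linear
program. Two objectives are screened: a **biomass** pseudo-reaction that
drains growth precursors (proliferation proxy, used for cancer models) and
an **ATP maintenance** pseudo-reaction that hydrolyses ATP (energy-balance
proxy, used for control models). Exchange reactions follow the
secretion-positive sign convention: uptake runs at negative flux, and a
growth medium is imposed by bounding each exchangeable metabolite's uptake
(metabolites absent from the medium cannot be taken up at all).

The LPs are solved by a two-phase bounded-variable primal simplex
implemented in the package. FBA systems are maximally degenerate — the
steady-state right-hand side is zero — so the implementation uses Bland's
anti-cycling pivot rule throughout and treats bound flips of nonbasic
variables as ordinary ratio-test outcomes. During development the solver
was checked against an independent interior-point/active-set implementation
on randomly generated bounded LPs, including infeasible instances.

### Flux consistency and context extraction

Not every reaction of a generic reconstruction can carry flux: dead ends
and orphans are structurally blocked. A reaction is **flux-consistent** if
it can carry $|v_i| \ge \varepsilon$ in some steady-state solution.
`fastcc()` finds the consistent set with the established iterative LP
scheme: jointly push candidate sets above $\varepsilon$ (the "LP7"
program), reorient unsupported reversible candidates by negating their
column and swapping bounds, and discard candidates supportable in neither
orientation. The acceptance suite verifies `fastcc()` against brute-force
per-reaction flux maximisation on randomly generated networks.

`fastcore_extract()` builds a context-specific model: given a consistent
parent network and a **core** of reactions that expression evidence
requires to be active, it returns a small flux-consistent subnetwork
containing the whole core, by alternating LP7 on the pending core with an
L1-penalised program ("LP10") that reproduces the core activity while
minimising support among non-core reactions. The result is near-minimal,
not guaranteed minimal; the test suite bounds it within one reaction of the
exhaustively-searched minimum on small fixtures. One numerical subtlety is
worth recording: LP10 pins satisfied core reactions a full $\varepsilon$
above zero while support membership is cut at $0.99\,\varepsilon$; pinning
at the cut itself makes membership of marginal reactions depend on
floating-point ties.

### From expression to cores

Expression values (FPKM-like, nonnegative) are discretized per sample.
A two-component Gaussian mixture is fitted to $\log_2(x+1)$ of the
nonzero values (via **mclust**); the lower component collects silent
genes, the upper component expressed ones. Two cuts are placed between the
component means $\mu_{lo} < \mu_{hi}$ at interpolation fractions
`zone = c(0.4, 0.6)`:

* $x \ge \mu_{lo} + 0.6\,(\mu_{hi}-\mu_{lo})$ — **expressed** (boundary
  inclusive upward),
* $x < \mu_{lo} + 0.4\,(\mu_{hi}-\mu_{lo})$ — **not expressed** (zeros
  always are),
* in between — **unknown**.

Placing the cuts strictly between the means, rather than at the means
themselves, is a deliberate design choice: with cuts at the component
means, half of each mode's mass lands in the unknown zone by construction,
and on well-separated data the genuinely bimodal signal would be discarded.
The interpolated cuts classify everything beyond ±4 standard deviations of
the means unambiguously while retaining an abstention band for genuinely
intermediate values; `zone = c(0, 1)` restores the strict means-as-bounds
behaviour for users who want maximal caution. A sample whose mixture
degenerates (components closer than `sep_floor = 1` log2 unit, or a failed
fit) falls back to a single global percentile cut with a warning.

A reaction is **core** for a sample iff it has a gene-protein-reaction
(GPR) rule and that rule evaluates true with expressed genes active;
unknown-zone genes count as inactive (conservative, configurable at the
calls level). Reactions without a GPR — transports, spontaneous reactions —
are never core but remain available as scaffold for the extraction to add.
Two kinds of models are built per dataset: **sample-specific** models (one
per RNA-seq sample) and a **consensus** model whose core contains the
reactions that are core in at least 90% of samples (inclusive boundary:
9 of 10 qualifies — with the strict reading, sampling grids that hit the
boundary exactly behave pathologically). The condition's objective reaction
is always appended to the core: a model that cannot run its screening
objective cannot be screened at all.

### Deletion screening

Gene knockouts follow the GPR rules: a reaction is inactivated when its
rule evaluates false under the deleted gene set, and inactivated reactions
have their bounds closed to $[0,0]$ (bound closure, not structural removal,
so wild type and knockout share one LP structure). A **drug deletion**
inactivates all of a drug's mapped targets simultaneously — the reason this
differs from single-gene analysis is the isozyme pair: a reaction gated by
`g1 or g2` survives either single deletion but dies when a drug hits both.
Only inhibitory drug-target relations are modelled. The outcome of each
deletion is the **growth ratio** (knockout objective / wild-type objective),
clipped to $[0,1]$ after verifying the knockout did not improve the
objective; an infeasible knockout LP scores 0 (a knockout that destroys
feasibility destroys growth). Contexts whose wild-type optimum does not
exceed $\varepsilon$ are unscreenable and are excluded from all score
denominators.

### Scoring and safety filtering

The decision thresholds (all configurable through `thresholds()`):

| parameter | default | meaning |
|---|---|---|
| `cancer_ratio_max` | 0.5 | knockout is effective when the cancer ratio is **strictly below** this |
| `healthy_ratio_min` | 0.9 | control model is protected when its ratio stays **at or above** this |
| `cancer_sample_fraction_min` | 0.5 | minimal fraction of affected cancer sample models (inclusive) |
| `healthy_sample_fraction_max` | 0.1 | maximal tolerated fraction of harmed control models (inclusive) |
| `consensus_activity_fraction` | 0.9 | core-in-fraction-of-samples rule for consensus models (inclusive) |

On consensus models an entity is essential iff it is effective on the
cancer model **and** protective on the control model. On sample-specific
models the efficacy fraction must reach `cancer_sample_fraction_min` while
the harm fraction (control models dropping below `healthy_ratio_min`) stays
within `healthy_sample_fraction_max`. The harm-bounded reading of the
control clause is itself a design decision: the alternative literal reading
("ratios preserved in at least 10% of controls") would declare almost any
knockout safe and would strip the control arm of its purpose as a safety
filter.

The **drug essentiality score** is the fraction of screenable sample models
in which the drug pushes the objective below the condition's threshold;
a score of 1 means the drug works in 100% of samples. Its reciprocal,
rounded up, is the **number needed to treat** (NNT) estimate. Candidate
drug sets are tested for over-representation of annotated anticancer drugs
with a one-sided hypergeometric test (Benjamini–Hochberg corrected across
datasets), and candidate sets from independently screened datasets are
intersected — datasets are never pooled, since cross-dataset batch effects
would contaminate pooled models.

## The synthetic study

`synthetic_spec()` defines a fully seeded toy study used by the test suite
and the acceptance script. The network plants one instance of every
mechanism the screen must handle:

* a **cancer pathway**: a serial, gene-gated chain (genes `gc1`, `gc2` by
  default) from the carbon source to the biomass precursor, expressed only
  in tumour samples — these genes are the planted essential set;
* an **isozyme pair** (`giso1 or giso2`) on the final precursor step —
  individually dispensable, jointly lethal;
* `n_pathways = 2` parallel **energy routes** feeding ATP maintenance,
  expressed everywhere, so no single energy gene is ever selective;
* a GPR-free **scaffold transport**, a **dead-end** reaction and an orphan
  exchange (the latter two are flux-inconsistent and must be dropped by
  `fastcc()`).

The medium supplies the primary nutrient at 20 and the secondary nutrient
at 10 mmol/gDW/h, chosen so that losing one energy route degrades growth
(ratio ≈ 0.67) without crossing the 0.5 essentiality cut — boundary
behaviour is exercised deliberately in unit tests, not left to chance in
the generator. The cohort has 28 cancer and 3 control samples, a realistic ratio for a tumour cohort
paired with a small healthy control arm. Expression emulates FPKM through
$2^z - 1$ with $z$ drawn from normal modes at 9 (expressed) and 1 (silent),
sd 1 — an 8-sd separation, comfortably above the 4-sd floor the spec object
enforces — plus 200 background genes (half constitutively on, half off)
that stabilise the per-sample mixture fit. The drug catalogue plants two
selective drugs (chain inhibitor; isozyme-pair inhibitor), one toxic drug
(hits every energy route, so the control arm must reject it), and three
inert decoys (single isozyme; a target absent from the network; the
dead-end gene).

What the generator does **not** emulate: expression noise that correlates
across genes or samples, batch effects, partial GPR coverage mismatches,
dosage effects (knockouts are binary), or the size of a genome-scale
reconstruction. Passing the planted-truth tests therefore demonstrates the
correctness of the pipeline's logic under clean conditions, not its
robustness on real cohorts.

## Numerical choices

* Flux-activity threshold $\varepsilon = 10^{-4}$ in model flux units;
  feasibility tolerance $10^{-7}$ for the mass-balance residual check.
  Both are exposed as arguments; the values match common constraint-based
  practice.
* Simplex pivot tolerance $10^{-9}$; phase-1 feasibility accepted below
  $10^{-7}$ total artificial value.
* Ratios are clipped to $[0,1]$ only after asserting
  `ko <= wt * (1 + 1e-6) + 1e-6`; a violation is an error, not a warning.
* Ties in the simplex are broken by Bland's smallest-index rule, which
  also makes every solve deterministic; the pipeline's outputs are a pure
  function of (inputs, configuration, seed), and the test suite asserts
  byte-identical reruns.
* Identical cores (common in clean cohorts) share one FASTCORE extraction
  and identical contexts share one screen, which is what keeps a 31-sample
  study in the test suite near-instant.

## Problem sizes

All shipped analyses are desk-scale by construction: the synthetic network
has 13 reactions and 8 genes (plus 200 background genes in the expression
matrix), random oracle-equivalence networks have at most ~12 reactions, and
exhaustive-minimality fixtures at most 6 non-core reactions. These sizes
were chosen so that every brute-force oracle (per-reaction LP enumeration,
exhaustive subset search, full truth tables) runs exactly, making the
dual-route tests sharp rather than statistical.

## Known limitations

* The simplex is dense and unfactorised (a fresh solve per basis change);
  it is intended for networks up to a few hundred reactions, not for
  Recon-scale models, where a sparse revised simplex or an external solver
  would be needed.
* SBML support covers the FBC subset used by constraint-based tools
  (species, bounds-as-parameters, gene-product associations, flux
  objectives); kinetic laws, annotations and units round-trip is out of
  scope.
* Replicate pooling for cell-line consensus models is treated as ordinary
  consensus building with the same activity fraction; workflows that pool
  replicates by averaging expression first should do so upstream.
* Drug action is modelled as complete inhibition of all targets; partial
  inhibition and non-inhibitory mechanisms are out of scope.
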