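# fluxscreen

Context-specific metabolic modelling and in silico drug-deletion screening
for cancer metabolism.

## What it does, and for whom

Proliferating tumour cells depend on metabolic pathways that quiescent
healthy tissue barely uses. `fluxscreen` turns that observation into a
drug-repurposing screen for computational biologists working with
constraint-based models: starting from a genome-scale metabolic
reconstruction, RNA-seq-style expression data and a drug–target table, it

1. **discretizes** expression per sample with a two-component Gaussian
   mixture on log2 values (expressed / unknown / not expressed),
2. **builds flux-consistent context-specific models** — one per sample,
   plus a consensus model from reactions active in ≥ 90% of a condition's
   samples — with the FASTCC consistency test and FASTCORE extraction,
3. **simulates deletions**: every gene singly, and every drug as the
   simultaneous knockout of all its targets through the boolean
   gene-protein-reaction (GPR) rules ("bounds to zero" closure),
4. **scores selectivity**: a knockout is a hit when it drops the biomass
   growth ratio of cancer models below 50% while ATP maintenance in
   control models stays at or above 90%, required in ≥ 50% of cancer and
   violated in ≤ 10% of control sample models,
5. **ranks drugs** by their essentiality score (fraction of sample models
   pushed below threshold), derives number-needed-to-treat (NNT)
   estimates, tests candidate sets for enrichment of annotated anticancer
   drugs (hypergeometric), and intersects candidates across independently
   screened datasets.

The core quantities, in the field's notation: flux balance analysis
maximises an objective flux subject to `S v = 0`, `lb ≤ v ≤ ub`; the growth
ratio of a deletion is `v*_ko / v*_wt`; the drug essentiality score is
`#{samples: ratio < threshold} / #{screenable samples}`; `NNT = ⌈1/score⌉`.

Everything runs on a bounded-variable two-phase simplex implemented in the
package (Bland's rule, deterministic), sized for desk-scale networks.
Model input/output covers SBML Level 3 FBC and a compact JSON dialect;
expression, calls, drugs and media travel as TSV.

## Worked example

The package ships a fully seeded synthetic study: a toy network with a
tumour-only biosynthesis chain, an isozyme pair, parallel energy routes,
a planted-toxic and two planted-selective drugs, plus 28 cancer and 3
control expression samples.

```r
library(fluxscreen)

spec <- synthetic_spec(seed = 1)
fx <- generate_fixture(spec)
fx$model
#> <metabolic_model 'synthetic'>
#>   10 metabolites, 13 reactions (4 exchanges), 8 genes
#>   biomass: BIOMASS   atp_maintenance: ATPM

calls <- discretize_expression(fx$expression)
cancer  <- build_sample_models(fx$model, calls[, grepl("^CAN", colnames(calls))],
                               fx$medium, "cancer")
control <- build_sample_models(fx$model, calls[, grepl("^CTL", colnames(calls))],
                               fx$medium, "control")
cancer[[1]]
#> <context_model of 'synthetic' [sample_specific:CAN01]> 11 reactions kept; biomass = 15 (viable)

outcomes <- screen_dataset(c(cancer, control), fx$drugs)
rep <- screen_report(outcomes)
head(as.data.frame(rep)[, c("entity_id", "entity_kind", "cancer_efficacy",
                            "control_harm", "sample_essential", "score", "nnt")], 6)
#>        entity_id entity_kind cancer_efficacy control_harm sample_essential score nnt
#> 1     D_ISO_PAIR        drug               1            0             TRUE     1   1
#> 2    D_SEL_CHAIN        drug               1            0             TRUE     1   1
#> 3          D_TOX        drug               1            1            FALSE     1   1
#> 4            gc1        gene               1            0             TRUE     1   1
#> 5            gc2        gene               1            0             TRUE     1   1
#> 6 D_DECOY_ABSENT        drug               0            0            FALSE     0  NA
```

Reading the table: the chain inhibitor `D_SEL_CHAIN` and the isozyme-pair
drug `D_ISO_PAIR` abolish growth in all 28 cancer models (efficacy 1,
score 1, NNT 1) without touching the controls — they are called essential.
`D_TOX` is just as potent against the tumour arm but wipes out ATP
maintenance in every control model (harm 1), so the safety filter rejects
it. The decoys score 0. Note `D_ISO_PAIR` is a hit although neither
`giso1` nor `giso2` is individually essential — the multi-target deletion
is what single-gene analysis cannot see.

The same analysis runs end-to-end from one config:

```r
cfg <- write_synthetic_inputs(synthetic_spec(seed = 1), "study")
res <- run_pipeline(cfg)   # writes report_*.tsv, efficacy_*.tsv,
                           # candidates.tsv, enrichment.tsv, run_log.json
```

or from the shell via the thin CLI in `inst/cli/fluxscreen.R`
(`synth`, `validate`, `discretize`, `build-models`, `screen`, `score`,
`run`).

## Package layout

- `R/gpr.R` — GPR parsing, evaluation, rendering
- `R/model.R`, `R/io.R`, `R/io-sbml.R` — model container, JSON/SBML/TSV IO
- `R/lp.R`, `R/fba.R` — simplex, FBA, medium, FASTCC
- `R/fastcore.R`, `R/context.R` — context extraction, discretization,
  sample/consensus model builders
- `R/deletion.R`, `R/scoring.R` — deletion screens, thresholds, scores,
  enrichment
- `R/synthetic.R`, `R/pipeline.R` — seeded fixture generator, end-to-end
  pipeline
- `vignettes/fluxscreen-methods.Rmd` — the methods vignette: model,
  assumptions, thresholds, numerical choices, limitations
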