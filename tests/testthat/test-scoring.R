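test_that("consensus essentiality uses strict cancer and inclusive healthy cuts", {
  th <- thresholds()
  expect_true(call_essential_consensus(0.4, 0.95, th))
  expect_false(call_essential_consensus(0.6, 0.95, th))   # cancer fails
  expect_false(call_essential_consensus(0.5, 0.95, th))   # "below 50%" strict
  expect_true(call_essential_consensus(0.49, 0.9, th))    # healthy inclusive
  expect_false(call_essential_consensus(0.49, 0.89, th))
  # missing control ratio: fail-safe by default, callable as pass
  expect_false(call_essential_consensus(0.1, NA, th))
  expect_true(call_essential_consensus(0.1, NA, th, missing_healthy = "pass"))
})

test_that("sample-level calls count screenable models on both arms", {
  th <- thresholds()
  # 28 fully hit cancer models, 3 untouched controls
  s <- call_essential_samples(rep(0, 28), rep(1, 3), th)
  expect_true(s$essential)
  expect_equal(s$cancer_efficacy, 1)
  expect_equal(s$control_harm, 0)
  expect_equal(s$n_cancer, 28)

  # 4 of 10 below the cancer cut: 0.4 < 0.5, not essential
  s2 <- call_essential_samples(c(rep(0, 4), rep(1, 6)), rep(1, 3), th)
  expect_false(s2$essential)
  expect_equal(s2$cancer_efficacy, 0.4)

  # exactly 50% of cancer models: inclusive, essential
  s3 <- call_essential_samples(c(rep(0, 5), rep(1, 5)), rep(1, 3), th)
  expect_true(s3$essential)

  # exactly 10% harmed controls: inclusive, still tolerated
  s4 <- call_essential_samples(rep(0, 4), c(rep(0, 1), rep(1, 9)), th)
  expect_equal(s4$control_harm, 0.1)
  expect_true(s4$essential)
  s5 <- call_essential_samples(rep(0, 4), c(rep(0, 2), rep(1, 8)), th)
  expect_false(s5$essential)

  # no controls supplied: undefined
  expect_true(is.na(call_essential_samples(rep(0, 4), numeric(), th)$essential))
  # unscreenable models are excluded from denominators
  s6 <- call_essential_samples(c(0, 0, NA, NA), rep(1, 3), th)
  expect_equal(s6$n_cancer, 2)
  expect_equal(s6$cancer_efficacy, 1)
})

test_that("drug essentiality score is the affected-sample fraction", {
  th <- thresholds()
  expect_equal(drug_essentiality_score(rep(0, 7), th), 1)
  expect_equal(drug_essentiality_score(rep(1, 7), th), 0)
  expect_equal(drug_essentiality_score(c(rep(0.2, 14), rep(0.9, 14)), th), 0.5)
  # the cancer cut is strict: ratio exactly 0.5 is not affected
  expect_equal(drug_essentiality_score(rep(0.5, 4), th), 0)
  # control arm uses the protection threshold
  expect_equal(drug_essentiality_score(c(0.85, 0.95), th, "control"), 0.5)
  expect_true(is.na(drug_essentiality_score(numeric(), th)))
})

test_that("NNT is the ceiling reciprocal of the efficacy fraction", {
  expect_identical(nnt_estimate(1), 1L)
  expect_identical(nnt_estimate(0.5), 2L)
  expect_identical(nnt_estimate(0.3), 4L)
  expect_identical(nnt_estimate(0), NA_integer_)
  expect_identical(nnt_estimate(NA_real_), NA_integer_)
  expect_error(nnt_estimate(1.5))
})

test_that("enrichment is the exact hypergeometric upper tail", {
  universe <- paste0("d", 1:10)
  annotated <- paste0("d", 1:5)
  e <- enrichment_score(paste0("d", 1:3), annotated, universe)
  expect_equal(e$p_value, choose(5, 3) / choose(10, 3))  # 10/120
  expect_equal(e$k, 3)

  expect_equal(enrichment_score(character(), annotated, universe)$p_value, 1)
  # no enrichment is possible when everything is annotated
  expect_equal(enrichment_score(paste0("d", 1:4), universe, universe)$p_value,
               1)
  expect_error(enrichment_score("dX", annotated, universe), "outside")
})

test_that("candidate intersection mirrors set algebra", {
  res <- intersect_candidates(list(D1 = c("a", "b", "c"), D2 = c("b", "c"),
                                   D3 = "c"))
  expect_identical(res$shared, "c")
  expect_identical(dim(res$membership), c(3L, 3L))
  expect_true(res$membership["c", "D3"])
  expect_false(res$membership["a", "D2"])

  expect_identical(intersect_candidates(list(D1 = c("x", "y")))$shared,
                   c("x", "y"))
  expect_length(intersect_candidates(list(D1 = "a", D2 = "b"))$shared, 0)
})

test_that("scores are permutation-invariant and thresholds monotone", {
  set.seed(31)
  ratios <- runif(20)
  th <- thresholds()
  for (i in 1:5) {
    perm <- sample(ratios)
    expect_equal(drug_essentiality_score(perm, th),
                 drug_essentiality_score(ratios, th))
  }
  # tightening the cancer cut never enlarges the essential set
  healthy <- rep(1, 5)
  cuts <- c(0.7, 0.5, 0.3, 0.1)
  essentials <- lapply(cuts, function(cut) {
    th2 <- thresholds(cancer_ratio_max = cut)
    which(vapply(ratios, function(r)
      call_essential_consensus(r, 1, th2), logical(1)))
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(essentials[[i]] %in% essentials[[i - 1]]))
  }
})

test_that("threshold objects validate their proportions", {
  expect_error(thresholds(cancer_ratio_max = 1.2), "proportion")
  expect_error(thresholds(healthy_ratio_min = -0.1), "proportion")
})

test_that("screen_report aggregates arms into per-entity rows", {
  ctx_can <- as_context(isozyme_model())
  ctx_can$provenance$id <- "C1"
  ctl_model <- chain_model()
  ctl_model$atp_maintenance <- "BIOMASS"  # reuse drain as the energy proxy
  ctx_ctl <- as_context(ctl_model, objective = "atp_maintenance")
  ctx_ctl$provenance$id <- "H1"
  drugs <- data.frame(drug_id = c("D_pair", "D_one"),
                      target_genes = c("g1;g2", "g1"),
                      is_anticancer = c(1L, 0L))
  out <- screen_dataset(list(ctx_can, ctx_ctl), drugs, genes = FALSE)
  rep <- screen_report(out)
  expect_s3_class(rep, "screen_report")
  pair <- rep[rep$entity_id == "D_pair", ]
  expect_equal(pair$cancer_efficacy, 1)
  expect_equal(pair$score, 1)
  expect_equal(pair$nnt, 1L)
  # the control model runs on g1, so D_pair harms it: safety filter trips
  expect_equal(pair$control_harm, 1)
  expect_false(pair$sample_essential)
  one <- rep[rep$entity_id == "D_one", ]
  expect_equal(one$cancer_efficacy, 0)    # isozyme backup in the cancer arm
})
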