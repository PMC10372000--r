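# calls matrix helper: genes x samples from a named list of expressed sets
calls_from_sets <- function(genes, expressed_per_sample) {
  samples <- names(expressed_per_sample)
  calls <- matrix(-1L, length(genes), length(samples),
                  dimnames = list(genes, samples))
  for (s in samples) calls[expressed_per_sample[[s]], s] <- 1L
  calls
}

test_that("reaction cores follow the GPR rules under ternary calls", {
  m <- metabolic_model(
    "core", c("A", "B", "C"),
    list(list(id = "R1", stoich = c(A = -1, B = 1), lb = 0, ub = 1,
              gpr = "g1 or g2"),
         list(id = "R2", stoich = c(B = -1, C = 1), lb = 0, ub = 1,
              gpr = "g1 and g2"),
         list(id = "T1", stoich = c(C = -1), lb = 0, ub = 1)))
  calls <- calls_from_sets(c("g1", "g2"),
                           list(S1 = "g1", S2 = c("g1", "g2"), S3 = character()))
  expect_identical(reaction_core_from_calls(m, calls, "S1"), "R1")
  expect_setequal(reaction_core_from_calls(m, calls, "S2"), c("R1", "R2"))
  expect_length(reaction_core_from_calls(m, calls, "S3"), 0)
  # unknown (0) counts as not expressed
  calls["g2", "S2"] <- 0L
  expect_identical(reaction_core_from_calls(m, calls, "S2"), "R1")
  # T1 has no GPR and is never core
  expect_false("T1" %in% reaction_core_from_calls(m, calls, "S2"))
  expect_error(reaction_core_from_calls(m, calls, "S9"), "unknown sample")
})

test_that("identical samples give identical sample-specific models", {
  sp <- synthetic_spec(seed = 2, n_samples_cancer = 5, n_samples_control = 0)
  fx <- generate_fixture(sp)
  calls <- ifelse(fx$truth == "expressed", 1L, -1L)  # noise-free calls
  ctxs <- build_sample_models(fx$model, calls, fx$medium, "cancer")
  expect_length(ctxs, 5)
  kept <- lapply(ctxs, `[[`, "kept")
  for (k in kept[-1]) expect_identical(k, kept[[1]])
  expect_true(all(vapply(ctxs, `[[`, logical(1), "viable")))
  # provenance records each sample despite the shared extraction
  expect_identical(
    vapply(ctxs, function(x) x$provenance$id, character(1), USE.NAMES = FALSE),
    colnames(calls))

  # determinism across runs
  ctxs2 <- build_sample_models(fx$model, calls, fx$medium, "cancer")
  expect_identical(lapply(ctxs2, `[[`, "kept"), kept)
})

test_that("cancer models force biomass, control models force ATP maintenance", {
  sp <- synthetic_spec(seed = 4, n_samples_cancer = 2, n_samples_control = 2)
  fx <- generate_fixture(sp)
  calls <- ifelse(fx$truth == "expressed", 1L, -1L)
  can <- build_sample_models(fx$model, calls[, 1:2], fx$medium, "cancer")
  ctl <- build_sample_models(fx$model, calls[, 3:4], fx$medium, "control")
  expect_true(all(vapply(can, function(x) "BIOMASS" %in% x$kept, logical(1))))
  expect_true(all(vapply(ctl, function(x) "ATPM" %in% x$kept, logical(1))))
  # the control profile silences the cancer pathway, so it is absent
  expect_false(any(vapply(ctl, function(x) "R_C1" %in% x$kept, logical(1))))
  expect_identical(unique(vapply(can, `[[`, character(1), "objective_kind")),
                   "biomass")
  expect_identical(unique(vapply(ctl, `[[`, character(1), "objective_kind")),
                   "atp_maintenance")
})

test_that("consensus activity counting is inclusive at the 90% boundary", {
  m <- metabolic_model(
    "cons", c("A", "B"),
    list(list(id = "EX_A", stoich = c(A = -1), lb = -10, ub = 10),
         list(id = "R1", stoich = c(A = -1, B = 1), lb = 0, ub = 10,
              gpr = "g1"),
         list(id = "R2", stoich = c(A = -1, B = 1), lb = 0, ub = 10,
              gpr = "g2"),
         list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 10)),
    biomass = "BIOMASS")
  samples <- sprintf("S%02d", 1:10)
  # g1 expressed in 9/10 samples (exactly 90%), g2 in 5/10
  sets <- lapply(seq_along(samples), function(i) {
    c(if (i <= 9) "g1", if (i <= 5) "g2")
  })
  names(sets) <- samples
  calls <- calls_from_sets(c("g1", "g2"), sets)
  cons <- build_consensus_model(m, calls, condition = "cancer")
  expect_true("R1" %in% cons$kept)       # 0.9 >= 0.9, inclusive
  expect_false("R2" %in% cons$kept)      # 0.5 < 0.9
  # core in 10/10 is trivially included
  calls10 <- calls_from_sets("g1", stats::setNames(
    rep(list("g1"), 10), samples))
  cons10 <- build_consensus_model(m, calls10, condition = "cancer")
  expect_true("R1" %in% cons10$kept)
  expect_error(build_consensus_model(m, calls[, 0, drop = FALSE],
                                     condition = "cancer"),
               "at least one sample")
})

test_that("consensus kept set is contained in the union of sample models", {
  sp <- synthetic_spec(seed = 8, n_samples_cancer = 6, n_samples_control = 0)
  fx <- generate_fixture(sp)
  calls <- discretize_expression(fx$expression)
  ctxs <- build_sample_models(fx$model, calls, fx$medium, "cancer")
  cons <- build_consensus_model(fx$model, calls, fx$medium, "cancer")
  expect_true(all(cons$kept %in% unique(unlist(lapply(ctxs, `[[`, "kept")))))
})

test_that("a blocked objective aborts model building", {
  m <- chain_model()  # biomass only; no ATP maintenance declared
  calls <- calls_from_sets("g1", list(S1 = "g1"))
  expect_error(build_sample_models(m, calls, condition = "control"),
               "atp_maintenance")
  # starving the model blocks biomass itself
  empty_med <- stats::setNames(numeric(), character())
  expect_error(build_sample_models(m, calls, empty_med, "cancer"),
               "absent or blocked")
})
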