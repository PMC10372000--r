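test_that("the spec validates its study conditions", {
  expect_error(synthetic_spec(), "seed is mandatory")
  expect_error(synthetic_spec(seed = 1, expressed_log2_mean = 4,
                              silent_log2_mean = 1),
               "4 standard deviations")
  sp <- synthetic_spec(seed = 1)
  expect_identical(sp$planted_essential_genes, c("gc1", "gc2"))
  expect_equal(sp$n_samples_cancer, 28)
  expect_equal(sp$n_samples_control, 3)
})

test_that("generators are bit-reproducible under a fixed seed", {
  sp <- synthetic_spec(seed = 123)
  fx1 <- generate_fixture(sp)
  fx2 <- generate_fixture(sp)
  expect_identical(fx1$model[setdiff(names(fx1$model), "gpr")],
                   fx2$model[setdiff(names(fx2$model), "gpr")])
  expect_identical(fx1$expression, fx2$expression)
  expect_identical(fx1$truth, fx2$truth)
  expect_identical(fx1$drugs, fx2$drugs)
  # a different seed moves the continuous values but not the structure
  fx3 <- generate_fixture(synthetic_spec(seed = 124))
  expect_false(identical(fx1$expression, fx3$expression))
  expect_identical(fx1$truth, fx3$truth)
})

test_that("the network plants the advertised structure", {
  sp <- synthetic_spec(seed = 6)
  m <- generate_network(sp)
  med <- synthetic_medium(sp)
  nm <- apply_medium(m, med)
  # planted essential gene kills biomass but spares ATP maintenance
  shut <- inactivate_for_genes(nm, "gc1")
  expect_equal(fba_optimize(nm, "biomass", disabled = shut)$objective_value, 0)
  expect_gt(fba_optimize(nm, "atp_maintenance",
                         disabled = shut)$objective_value, 0)
  # the isozyme pair is lethal only jointly
  expect_gt(fba_optimize(nm, "biomass",
    disabled = inactivate_for_genes(nm, "giso1"))$objective_value, 0)
  expect_equal(fba_optimize(nm, "biomass",
    disabled = inactivate_for_genes(nm, c("giso1", "giso2")))$objective_value,
    0)
  # scaffold transport has no GPR
  expect_null(m$gpr[["T_A"]])
  # consistency drops exactly the dead end and the orphan exchange
  expect_setequal(setdiff(nm$rxns, fastcc(nm)), c("R_DEAD", "EX_U"))
})

test_that("expression emulates the planted on/off structure", {
  sp <- synthetic_spec(seed = 55)
  fx <- generate_fixture(sp)
  expect_equal(ncol(fx$expression), 31)
  expect_true(all(fx$expression >= 0))
  # cancer pathway genes are silent in controls, expressed in tumours
  expect_true(all(fx$truth["gc1", grepl("^CAN", colnames(fx$truth))] ==
                    "expressed"))
  expect_true(all(fx$truth["gc1", grepl("^CTL", colnames(fx$truth))] ==
                    "silent"))
  expect_true(all(fx$truth["ge1", ] == "expressed"))

  # discretization recovers the labels: no contradictions at this separation
  calls <- discretize_expression(fx$expression)
  truth <- ifelse(fx$truth == "expressed", 1L, -1L)
  flips <- sum(calls != 0L & calls != truth)
  expect_identical(flips, 0L)
  expect_lt(mean(calls == 0L), 0.01)   # abstentions are rare

  # swapping the modes inverts every decided call
  sp_sw <- synthetic_spec(seed = 55)
  sp_sw$expressed_log2_mean <- sp$silent_log2_mean
  sp_sw$silent_log2_mean <- sp$expressed_log2_mean
  fx_sw <- generate_expression(sp_sw, generate_network(sp_sw))
  calls_sw <- discretize_expression(fx_sw$expression)
  both <- calls != 0L & calls_sw != 0L & fx_sw$expression > 0
  expect_true(all(calls[both] == -calls_sw[both]))
})

test_that("cohort size zero drops the corresponding columns", {
  sp <- synthetic_spec(seed = 3, n_samples_cancer = 0)
  fx <- generate_expression(sp, generate_network(sp))
  expect_true(all(grepl("^CTL", colnames(fx$expression))))
})

test_that("the drug catalogue plants selective, toxic and inert drugs", {
  sp <- synthetic_spec(seed = 10)
  m <- generate_network(sp)
  dt <- generate_drug_table(sp, m)
  expect_setequal(dt$drugs$drug_id,
                  c(dt$truth$selective, dt$truth$toxic, dt$truth$inert))
  tl <- drug_targets(dt$drugs)
  nm <- apply_medium(m, synthetic_medium(sp))
  # toxic drug abolishes control energy balance
  expect_equal(fba_optimize(nm, "atp_maintenance",
    disabled = inactivate_for_genes(nm, tl$D_TOX))$objective_value, 0)
  # decoys touch nothing that matters
  expect_length(intersect(tl$D_DECOY_ABSENT, m$genes), 0)
  expect_equal(fba_optimize(nm, "biomass",
    disabled = inactivate_for_genes(nm, tl$D_DECOY_DEAD))$objective_value,
    fba_optimize(nm, "biomass")$objective_value)
  # anticancer annotation marks exactly the selective drugs
  expect_setequal(dt$drugs$drug_id[dt$drugs$is_anticancer == 1L],
                  dt$truth$selective)
})
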