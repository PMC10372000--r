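test_that("flux maxima match hand-computed linear programs", {
  m <- chain_model()
  sol <- fba_optimize(m, "biomass")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)           # uptake-limited chain
  expect_equal(unname(sol$fluxes["EX_A"]), -10)   # uptake runs negative
  expect_lte(max(abs(m$S %*% sol$fluxes)), 1e-7)  # steady state

  expect_equal(fba_optimize(m, "biomass", disabled = "R1")$objective_value, 0)

  # parallel routes with capacities 5 and 7
  expect_equal(fba_optimize(parallel_model(10), "biomass")$objective_value, 10)
  expect_equal(fba_optimize(parallel_model(20), "biomass")$objective_value, 12)
})

test_that("infeasible problems score objective zero", {
  # forced internal flux with every source shut
  m <- metabolic_model(
    "inf", c("A", "B"),
    list(list(id = "EX_A", stoich = c(A = -1), lb = 0, ub = 0),
         list(id = "R1", stoich = c(A = -1, B = 1), lb = 2, ub = 5),
         list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 100)),
    biomass = "BIOMASS")
  sol <- fba_optimize(m, "biomass")
  expect_equal(sol$status, "infeasible")
  expect_equal(sol$objective_value, 0)
})

test_that("unknown objectives and reactions raise errors", {
  m <- chain_model()
  expect_error(fba_optimize(m, "atp_maintenance"), "does not name a reaction")
  expect_error(fba_optimize(m, "biomass", disabled = "NOPE"), "unknown")
})

test_that("the optimum is invariant under reaction and metabolite order", {
  m <- random_toy_model(23)
  ref <- fba_optimize(m, "biomass")$objective_value
  set.seed(99)
  for (i in 1:5) {
    perm <- sample(m$rxns)
    reactions <- lapply(perm, function(rid) {
      st <- m$S[, rid]
      list(id = rid, stoich = st[st != 0], lb = m$lb[[rid]],
           ub = m$ub[[rid]], gpr = m$gpr[[rid]])
    })
    m2 <- metabolic_model(m$id, sample(m$mets), reactions, genes = m$genes,
                          biomass = "BIOMASS")
    expect_equal(fba_optimize(m2, "biomass")$objective_value, ref,
                 tolerance = 1e-9)
  }
})

test_that("disabling reactions never increases the optimum", {
  for (seed in c(2, 12, 31)) {
    m <- random_toy_model(seed)
    base <- fba_optimize(m, "biomass")$objective_value
    for (r in setdiff(m$rxns, "BIOMASS")) {
      expect_lte(fba_optimize(m, "biomass", disabled = r)$objective_value,
                 base + 1e-8)
    }
  }
})

test_that("medium application opens listed uptakes and closes the rest", {
  m <- metabolic_model(
    "med", c("A", "B", "C"),
    list(list(id = "EX_A", stoich = c(A = -1), lb = -99, ub = 99),
         list(id = "EX_B", stoich = c(B = -1), lb = -99, ub = 99),
         list(id = "R1", stoich = c(A = -1, C = 1), lb = 0, ub = 99),
         list(id = "BIOMASS", stoich = c(C = -1), lb = 0, ub = 99)),
    biomass = "BIOMASS")
  m2 <- apply_medium(m, c(A = 10))
  expect_equal(unname(m2$lb["EX_A"]), -10)
  expect_equal(unname(m2$lb["EX_B"]), 0)     # uptake closed
  expect_equal(unname(m2$ub["EX_B"]), 99)    # secretion untouched

  # empty medium starves any uptake-dependent objective
  m3 <- apply_medium(m, stats::setNames(numeric(), character()))
  expect_equal(fba_optimize(m3, "biomass")$objective_value, 0)

  # a medium key with no exchange warns and changes nothing
  expect_warning(m4 <- apply_medium(m, c(A = 10, ZZZ = 5)),
                 "no exchange reaction")
  expect_equal(m4$lb, m2$lb)
  expect_equal(m4$ub, m2$ub)

  expect_error(apply_medium(m, c(A = -1)), "nonnegative")
})
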