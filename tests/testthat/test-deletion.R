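test_that("single-gene deletion reproduces hand-computed growth ratios", {
  ctx <- as_context(chain_model())
  out <- single_gene_deletion(ctx)
  expect_equal(out$entity_id, "g1")
  expect_equal(out$wt_objective, 10)
  expect_equal(out$ratio, 0)          # R1 is the only biomass route

  # a gene absent from every GPR leaves the optimum untouched
  out2 <- single_gene_deletion(ctx, genes = c("g1", "g_absent"))
  expect_equal(out2$ratio[out2$entity_id == "g_absent"], 1)

  # isozymes back each other up
  iso <- as_context(isozyme_model())
  out3 <- single_gene_deletion(iso)
  expect_equal(out3$ratio, c(1, 1))
})

test_that("drug deletion shuts all targets at once", {
  iso <- as_context(isozyme_model())
  hit <- drug_deletion(iso, "D_pair", c("g1", "g2"))
  expect_equal(hit$ratio, 0)          # multi-target synthetic lethality
  expect_false(hit$no_target)

  # a drug with no mapped target is inert and flagged
  none <- drug_deletion(iso, "D_none", "gX")
  expect_equal(none$ratio, 1)
  expect_true(none$no_target)

  # single-target drug reduces to the single-gene deletion
  ctx <- as_context(chain_model())
  expect_equal(drug_deletion(ctx, "D_g1", "g1")$ratio,
               single_gene_deletion(ctx)$ratio)
})

test_that("screening a non-viable context is an error", {
  ctx <- as_context(chain_model())
  ctx$viable <- FALSE
  expect_error(single_gene_deletion(ctx), "not viable")
  ctx$viable <- TRUE
  ctx$objective_kind <- NA_character_
  expect_error(single_gene_deletion(ctx), "no screening objective")
})

test_that("screen_dataset yields the full deterministic cross product", {
  contexts <- list(as_context(chain_model()),
                   as_context(isozyme_model()),
                   as_context(two_path_model()))
  drugs <- data.frame(drug_id = c("d1", "d2", "d3", "d4"),
                      target_genes = c("g1", "g2", "g1;g2", "gX"),
                      is_anticancer = c(1L, 0L, 0L, 0L))
  out <- screen_dataset(contexts, drugs, genes = FALSE)
  expect_equal(nrow(out), 12)                    # 3 contexts x 4 drugs
  out_again <- screen_dataset(contexts, drugs, genes = FALSE)
  expect_identical(out, out_again)

  # identical contexts produce identical outcome rows
  c1 <- as_context(isozyme_model())
  c2 <- as_context(isozyme_model())
  c1$provenance$id <- "S1"
  c2$provenance$id <- "S2"
  twin <- screen_dataset(list(c1, c2), drugs, genes = FALSE)
  a <- twin[twin$context_id == "S1", -1]
  b <- twin[twin$context_id == "S2", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("unscreenable contexts are flagged and carry NA ratios", {
  ctx <- as_context(chain_model())
  ctx$viable <- FALSE
  out <- screen_dataset(list(ctx), genes = "g1")
  expect_false(out$screenable)
  expect_true(is.na(out$ratio))
})

test_that("deletion ratios match the brute-force enumerator", {
  set.seed(555)
  for (seed in c(6, 13, 29)) {
    m <- random_toy_model(seed)
    cons <- subset_model(m, fastcc(m))
    if (!("BIOMASS" %in% cons$rxns)) next
    ctx <- as_context(cons)
    out <- single_gene_deletion(ctx)
    for (i in seq_len(nrow(out))) {
      expect_equal(out$ratio[i],
                   oracle_deletion_ratio(cons, out$entity_id[i], "biomass"),
                   tolerance = 1e-6,
                   info = sprintf("seed %d gene %s", seed, out$entity_id[i]))
    }
    targets <- sample(m$genes, 2)
    d <- drug_deletion(ctx, "D", targets)
    expect_equal(d$ratio, oracle_deletion_ratio(cons, targets, "biomass"),
                 tolerance = 1e-6)
  }
})

test_that("ratios are bounded and drugs are at most as mild as their targets", {
  for (seed in c(7, 19)) {
    m <- random_toy_model(seed)
    cons <- subset_model(m, fastcc(m))
    if (!("BIOMASS" %in% cons$rxns)) next
    ctx <- as_context(cons)
    singles <- single_gene_deletion(ctx)
    expect_true(all(singles$ratio >= 0 & singles$ratio <= 1))
    expect_true(all(singles$ko_objective <=
                      singles$wt_objective * (1 + 1e-6) + 1e-6))
    d <- drug_deletion(ctx, "D_all", m$genes)
    expect_lte(d$ratio, min(singles$ratio) + 1e-6)
  }
})
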