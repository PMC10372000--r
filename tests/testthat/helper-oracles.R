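# Independent oracles used across the suite. These deliberately avoid the
# package's GPR evaluator and screening loops: rules are evaluated by
# substituting into an R boolean expression, consistency and deletion
# outcomes are found by direct per-reaction LP enumeration.

# evaluate a GPR rule string by textual substitution into an R expression
oracle_eval_gpr <- function(rule_text, active_genes, all_genes) {
  if (!nzchar(trimws(rule_text))) return(TRUE)
  expr_txt <- rule_text
  expr_txt <- gsub("\\band\\b", "&&", expr_txt, ignore.case = TRUE)
  expr_txt <- gsub("\\bor\\b", "||", expr_txt, ignore.case = TRUE)
  env <- new.env(parent = baseenv())
  for (g in all_genes) assign(g, g %in% active_genes, envir = env)
  isTRUE(eval(parse(text = expr_txt), envir = env))
}

# raw LP optimum of one reaction's flux (direction = 1 max, -1 min)
oracle_flux_extreme <- function(model, rid, direction, disabled = character()) {
  lb <- model$lb
  ub <- model$ub
  lb[disabled] <- 0
  ub[disabled] <- 0
  obj <- as.numeric(model$rxns == rid) * direction
  sol <- fluxscreen:::.solve_lp(obj, unname(lb), unname(ub), Aeq = model$S,
                                beq = rep(0, nrow(model$S)), maximize = TRUE)
  if (sol$status != "optimal") return(NA_real_)
  sum(obj * sol$x) * direction
}

# brute-force flux consistency: a reaction is consistent iff it can carry
# |flux| >= epsilon in some steady-state solution
oracle_consistent <- function(model, epsilon = 1e-4) {
  keep <- vapply(model$rxns, function(rid) {
    mx <- oracle_flux_extreme(model, rid, 1)
    if (!is.na(mx) && mx >= epsilon - 1e-9) return(TRUE)
    mn <- oracle_flux_extreme(model, rid, -1)
    !is.na(mn) && mn <= -(epsilon - 1e-9)
  }, logical(1))
  model$rxns[keep]
}

# brute-force deletion: decide shut reactions by re-evaluating every GPR
# string with the oracle evaluator, then re-solve the objective LP
oracle_deletion_ratio <- function(model, inactive_genes, objective) {
  rid <- if (objective == "biomass") model$biomass
    else if (objective == "atp_maintenance") model$atp_maintenance
    else objective
  opt <- function(disabled) {
    v <- oracle_flux_extreme(model, rid, 1, disabled)
    if (is.na(v)) 0 else v
  }
  wt <- opt(character())
  active <- setdiff(model$genes, inactive_genes)
  shut <- model$rxns[vapply(model$rxns, function(r) {
    txt <- fluxscreen::render_gpr(model$gpr[[r]])
    nzchar(txt) && !oracle_eval_gpr(txt, active, model$genes)
  }, logical(1))]
  ko <- opt(shut)
  if (wt <= 1e-4) return(NA_real_)
  min(max(ko / wt, 0), 1)
}

# seeded random toy network: a guaranteed nutrient-to-biomass chain plus
# random side reactions (some dead ends), random GPRs, some reversible
random_toy_model <- function(seed, n_extra = 4, n_genes = 5) {
  set.seed(seed)
  k <- sample(2:4, 1)
  mets <- paste0("M", 0:k)
  genes <- paste0("g", seq_len(n_genes))
  rand_gpr <- function() {
    gs <- sample(genes, 3)
    switch(sample.int(5, 1),
           "",
           gs[1],
           paste(gs[1], "or", gs[2]),
           paste(gs[1], "and", gs[2]),
           sprintf("(%s and %s) or %s", gs[1], gs[2], gs[3]))
  }
  rxns <- list(list(id = "EX0", stoich = c(M0 = -1), lb = -10, ub = 100))
  for (i in seq_len(k)) {
    rxns[[length(rxns) + 1L]] <- list(
      id = paste0("C", i),
      stoich = stats::setNames(c(-1, 1), c(mets[i], mets[i + 1])),
      lb = if (stats::runif(1) < 0.25) -100 else 0, ub = 100,
      gpr = rand_gpr())
  }
  extra_mets <- character()
  for (j in seq_len(n_extra)) {
    from <- sample(mets, 1)
    if (stats::runif(1) < 0.4) {        # dead-end branch
      dm <- paste0("D", j)
      extra_mets <- c(extra_mets, dm)
      st <- stats::setNames(c(-1, 1), c(from, dm))
    } else {                            # shortcut / parallel edge
      to <- sample(setdiff(mets, from), 1)
      st <- stats::setNames(c(-1, 1), c(from, to))
    }
    rxns[[length(rxns) + 1L]] <- list(
      id = paste0("E", j), stoich = st,
      lb = if (stats::runif(1) < 0.2) -100 else 0, ub = 100,
      gpr = rand_gpr())
  }
  rxns[[length(rxns) + 1L]] <- list(
    id = "BIOMASS", stoich = stats::setNames(-1, mets[k + 1]),
    lb = 0, ub = 100)
  fluxscreen::metabolic_model(paste0("toy", seed), c(mets, extra_mets),
                              rxns, genes = genes, biomass = "BIOMASS")
}

# exhaustive minimum-cardinality flux-consistent superset of the core
# (searched by increasing size over additions from the non-core set)
oracle_min_consistent_superset <- function(model, core, epsilon = 1e-4) {
  noncore <- setdiff(model$rxns, core)
  self_consistent <- function(keep) {
    sub <- fluxscreen::subset_model(model, keep)
    length(oracle_consistent(sub, epsilon)) == length(keep)
  }
  for (extra in 0:length(noncore)) {
    combos <- utils::combn(noncore, extra, simplify = FALSE)
    for (add in combos) {
      keep <- c(core, add)
      if (self_consistent(keep)) return(length(keep))
    }
  }
  stop("no consistent superset exists")
}

# convenience fixtures ------------------------------------------------------

chain_model <- function() fluxscreen::example_chain_model()

# two alternative routes to the biomass precursor: one long (3 reactions),
# one short (1 reaction)
two_path_model <- function() {
  fluxscreen::metabolic_model(
    "twopath",
    metabolites = c("A", "I1", "I2", "B"),
    reactions = list(
      list(id = "EX_A", stoich = c(A = -1), lb = -10, ub = 100),
      list(id = "L1", stoich = c(A = -1, I1 = 1), lb = 0, ub = 100),
      list(id = "L2", stoich = c(I1 = -1, I2 = 1), lb = 0, ub = 100),
      list(id = "L3", stoich = c(I2 = -1, B = 1), lb = 0, ub = 100),
      list(id = "SHORT", stoich = c(A = -1, B = 1), lb = 0, ub = 100),
      list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 100)),
    biomass = "BIOMASS")
}

# parallel capacity-limited routes (5 and 7) from a shared uptake
parallel_model <- function(uptake = 10) {
  fluxscreen::metabolic_model(
    "parallel",
    metabolites = c("A", "B"),
    reactions = list(
      list(id = "EX_A", stoich = c(A = -1), lb = -uptake, ub = 100),
      list(id = "P5", stoich = c(A = -1, B = 1), lb = 0, ub = 5),
      list(id = "P7", stoich = c(A = -1, B = 1), lb = 0, ub = 7),
      list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 100)),
    biomass = "BIOMASS")
}

# chain plus a dead-end side reaction
deadend_model <- function() {
  fluxscreen::metabolic_model(
    "deadend",
    metabolites = c("A", "B", "D"),
    reactions = list(
      list(id = "EX_A", stoich = c(A = -1), lb = -10, ub = 100),
      list(id = "R1", stoich = c(A = -1, B = 1), lb = 0, ub = 100),
      list(id = "R_dead", stoich = c(A = -1, D = 1), lb = 0, ub = 100),
      list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 100)),
    biomass = "BIOMASS")
}

# isozyme toy: single biomass route gated by "g1 or g2"
isozyme_model <- function() {
  fluxscreen::metabolic_model(
    "iso",
    metabolites = c("A", "B"),
    reactions = list(
      list(id = "EX_A", stoich = c(A = -1), lb = -10, ub = 100),
      list(id = "R_ISO", stoich = c(A = -1, B = 1), lb = 0, ub = 100,
           gpr = "g1 or g2"),
      list(id = "BIOMASS", stoich = c(B = -1), lb = 0, ub = 100)),
    biomass = "BIOMASS")
}

# wrap a bare model as a viable screening context
as_context <- function(model, objective = "biomass") {
  fluxscreen::fastcore_extract(
    model, core = model$rxns, epsilon = 1e-4, objective = objective,
    provenance = list(kind = "sample_specific", id = model$id))
}
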