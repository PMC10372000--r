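#' Specification of a synthetic screening fixture
#'
#' Describes a toy study: a small metabolic network with planted structure,
#' a cohort of cancer and control expression samples, and a drug catalogue
#' with planted selective, toxic and inert drugs. Every generator is a pure
#' function of this object, so a seed fixes the whole fixture bit for bit.
#'
#' The network always contains a gene-driven "cancer pathway" chain feeding
#' the biomass precursor (its genes are the planted essential genes), an
#' isozyme pair on the final precursor step (lethal only when both members
#' are hit, the multi-target case), `n_pathways` parallel energy routes
#' feeding ATP maintenance, a GPR-free nutrient transport (scaffold), a
#' dead-end reaction and an orphan exchange (both flux-inconsistent).
#'
#' @param seed Integer RNG seed (mandatory).
#' @param n_pathways Number of parallel energy routes (>= 2); default 2.
#' @param pathway_length Length of the cancer pathway chain; default 2.
#' @param n_samples_cancer,n_samples_control Cohort sizes; defaults 28 and
#'   3, a realistic tumour cohort paired with a small healthy control arm.
#' @param expressed_log2_mean,silent_log2_mean,log2_sd Parameters of the
#'   log2-scale expression mixture; the means must be separated by at least
#'   4 standard deviations so that discretization is unambiguous.
#' @param n_background_genes Non-model genes added to stabilise the
#'   per-sample mixture fit (half constitutively expressed, half silent).
#' @return A `synthetic_spec` list, including the derived planted-truth id
#'   lists (`planted_essential_genes`, `planted_selective_drugs`,
#'   `planted_toxic_drugs`, `planted_inert_drugs`).
#' @export
synthetic_spec <- function(seed, n_pathways = 2, pathway_length = 2,
                           n_samples_cancer = 28, n_samples_control = 3,
                           expressed_log2_mean = 9, silent_log2_mean = 1,
                           log2_sd = 1, n_background_genes = 200) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_pathways >= 2, pathway_length >= 1, n_samples_cancer >= 0,
            n_samples_control >= 0, log2_sd > 0)
  if (expressed_log2_mean - silent_log2_mean < 4 * log2_sd) {
    stop("expression modes must be separated by at least 4 standard ",
         "deviations for a guaranteed-recovery fixture", call. = FALSE)
  }
  chain_genes <- paste0("gc", seq_len(pathway_length))
  structure(list(
    seed = as.integer(seed),
    n_pathways = n_pathways, pathway_length = pathway_length,
    n_samples_cancer = n_samples_cancer,
    n_samples_control = n_samples_control,
    expressed_log2_mean = expressed_log2_mean,
    silent_log2_mean = silent_log2_mean, log2_sd = log2_sd,
    n_background_genes = n_background_genes,
    planted_essential_genes = chain_genes,
    planted_selective_drugs = c("D_SEL_CHAIN", "D_ISO_PAIR"),
    planted_toxic_drugs = "D_TOX",
    planted_inert_drugs = c("D_ISO_SINGLE", "D_DECOY_ABSENT", "D_DECOY_DEAD")
  ), class = "synthetic_spec")
}

#' Generate the synthetic metabolic network
#'
#' Deterministic (no randomness): the topology is fixed by the spec. See
#' [synthetic_spec()] for the planted structure. Exchange reactions use the
#' secretion-positive convention. The companion medium (see
#' [synthetic_medium()]) supplies the primary nutrient at 20 and each
#' secondary nutrient at 10 mmol/gDW/h, leaving slack so that losing a
#' single energy route degrades but does not abolish growth.
#'
#' @param spec A [synthetic_spec()].
#' @return A [metabolic_model] with `biomass` and `atp_maintenance` set.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  P <- spec$n_pathways
  L <- spec$pathway_length
  mets <- c("A[e]", "A[c]", "E[c]", "PQ[c]", "D[c]", "U[e]")
  if (L > 1) mets <- c(mets, paste0("X", seq_len(L - 1), "[c]"))
  if (P > 1) mets <- c(mets, paste0("N", 2:P, "[e]"), paste0("N", 2:P, "[c]"))
  chain_in <- c("A[c]", if (L > 1) paste0("X", seq_len(L - 1), "[c]"))
  chain_out <- c(if (L > 1) paste0("X", seq_len(L - 1), "[c]"), "PRE[c]")
  # the chain ends in the isozyme substrate PRE
  mets <- c(mets, "PRE[c]")
  rxns <- list(
    list(id = "EX_A", stoich = c("A[e]" = -1), lb = -100, ub = 100),
    list(id = "EX_U", stoich = c("U[e]" = -1), lb = -100, ub = 100),
    list(id = "T_A", stoich = c("A[e]" = -1, "A[c]" = 1), lb = 0, ub = 100),
    list(id = "R_E1", stoich = c("A[c]" = -1, "E[c]" = 1), lb = 0, ub = 100,
         gpr = "ge1"),
    list(id = "R_DEAD", stoich = c("A[c]" = -1, "D[c]" = 1), lb = 0,
         ub = 100, gpr = "gdead"),
    list(id = "R_ISO", stoich = c("PRE[c]" = -1, "PQ[c]" = 1), lb = 0,
         ub = 100, gpr = "giso1 or giso2"),
    list(id = "BIOMASS", stoich = c("PQ[c]" = -1, "E[c]" = -1), lb = 0,
         ub = 100),
    list(id = "ATPM", stoich = c("E[c]" = -1), lb = 0, ub = 100)
  )
  for (j in seq_len(L)) {
    rxns[[length(rxns) + 1L]] <- list(
      id = paste0("R_C", j),
      stoich = stats::setNames(c(-1, 1), c(chain_in[j], chain_out[j])),
      lb = if (j == 1) -100 else 0, ub = 100,  # first chain step reversible
      gpr = paste0("gc", j))
  }
  for (i in seq_len(P)[-1]) {
    ne <- paste0("N", i, "[e]")
    nc <- paste0("N", i, "[c]")
    rxns <- c(rxns, list(
      list(id = paste0("EX_N", i), stoich = stats::setNames(-1, ne),
           lb = -100, ub = 100),
      list(id = paste0("T_N", i), stoich = stats::setNames(c(-1, 1),
           c(ne, nc)), lb = 0, ub = 100, gpr = paste0("gt", i)),
      list(id = paste0("R_E", i), stoich = stats::setNames(c(-1, 1),
           c(nc, "E[c]")), lb = 0, ub = 100, gpr = paste0("ge", i))))
  }
  metabolic_model("synthetic", mets, rxns,
                  biomass = "BIOMASS", atp_maintenance = "ATPM")
}

#' @rdname generate_network
#' @export
synthetic_medium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  med <- c("A[e]" = 20)
  if (spec$n_pathways > 1) {
    extra <- rep(10, spec$n_pathways - 1)
    names(extra) <- paste0("N", 2:spec$n_pathways, "[e]")
    med <- c(med, extra)
  }
  med
}

#' Generate the synthetic expression matrix with truth labels
#'
#' Cancer samples express the cancer-pathway genes (chain and isozymes);
#' control samples silence them. Housekeeping genes (energy routes,
#' transports, the dead-end gene) are expressed in every sample, and
#' background genes are split between constitutive expression and silence.
#' Values emulate FPKM: `2^z - 1` (clamped at 0) with `z` drawn from the
#' spec's expressed or silent normal mode, so `log2(value + 1)` reproduces
#' the stated mixture.
#'
#' @param spec A [synthetic_spec()].
#' @param model The matching network from [generate_network()].
#' @return List with `expression` (genes x samples matrix) and `truth`
#'   (character matrix of `"expressed"`/`"silent"`, same shape).
#' @export
generate_expression <- function(spec, model) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cancer_genes <- c(spec$planted_essential_genes, "giso1", "giso2")
  housekeeping <- setdiff(model$genes, cancer_genes)
  nbg <- spec$n_background_genes
  bg <- if (nbg > 0) sprintf("bg%03d", seq_len(nbg)) else character()
  bg_on <- bg[seq_len(floor(nbg / 2))]
  genes <- c(sort(model$genes), bg)
  samples <- c(
    if (spec$n_samples_cancer > 0)
      sprintf("CAN%02d", seq_len(spec$n_samples_cancer)),
    if (spec$n_samples_control > 0)
      sprintf("CTL%02d", seq_len(spec$n_samples_control)))
  is_cancer_sample <- grepl("^CAN", samples)
  truth <- matrix("silent", length(genes), length(samples),
                  dimnames = list(genes, samples))
  truth[genes %in% housekeeping, ] <- "expressed"
  truth[genes %in% bg_on, ] <- "expressed"
  truth[genes %in% cancer_genes, is_cancer_sample] <- "expressed"
  set.seed(spec$seed)
  mu <- ifelse(truth == "expressed", spec$expressed_log2_mean,
               spec$silent_log2_mean)
  z <- stats::rnorm(length(mu), mean = as.vector(mu), sd = spec$log2_sd)
  vals <- pmax(2^z - 1, 0)
  expr <- matrix(vals, length(genes), length(samples),
                 dimnames = dimnames(truth))
  list(expression = expr, truth = truth)
}

#' Generate the synthetic drug catalogue with truth labels
#'
#' Deterministic. Planted drugs: `D_SEL_CHAIN` inhibits the first cancer
#' chain gene (selectively lethal), `D_ISO_PAIR` inhibits both isozymes
#' (lethal only as a pair), `D_TOX` inhibits every energy-route enzyme
#' (kills ATP maintenance in control models, so the safety filter must
#' reject it), `D_ISO_SINGLE` hits one isozyme only, `D_DECOY_ABSENT`
#' targets a gene absent from the network and `D_DECOY_DEAD` targets the
#' dead-end gene. Anticancer annotation marks exactly the selective drugs,
#' for the enrichment test.
#'
#' @param spec A [synthetic_spec()].
#' @param model The matching network.
#' @return List with `drugs` (a drug table, see [read_drug_table()]) and
#'   `truth` (list of `selective`, `toxic`, `inert` drug ids).
#' @export
generate_drug_table <- function(spec, model) {
  stopifnot(inherits(spec, "synthetic_spec"))
  energy_genes <- grep("^ge", model$genes, value = TRUE)
  drugs <- data.frame(
    drug_id = c("D_SEL_CHAIN", "D_ISO_PAIR", "D_ISO_SINGLE", "D_TOX",
                "D_DECOY_ABSENT", "D_DECOY_DEAD"),
    target_genes = c("gc1", "giso1;giso2", "giso1",
                     paste(energy_genes, collapse = ";"),
                     "g_absent", "gdead"),
    is_anticancer = c(1L, 1L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
  list(drugs = drugs,
       truth = list(selective = spec$planted_selective_drugs,
                    toxic = spec$planted_toxic_drugs,
                    inert = spec$planted_inert_drugs))
}

#' Generate the full synthetic fixture
#'
#' Convenience wrapper bundling network, medium, expression and drug
#' catalogue for one spec.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `spec`, `model`, `medium`, `expression`, `truth`
#'   (expression labels), `drugs`, `drug_truth`.
#' @export
generate_fixture <- function(spec) {
  model <- generate_network(spec)
  expr <- generate_expression(spec, model)
  dt <- generate_drug_table(spec, model)
  list(spec = spec, model = model, medium = synthetic_medium(spec),
       expression = expr$expression, truth = expr$truth,
       drugs = dt$drugs, drug_truth = dt$truth)
}
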