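#' Assemble and validate a pipeline run configuration
#'
#' A run configuration names the parent model, the drug table, the medium,
#' one or more expression datasets each tagged `cancer` or `control`, the
#' screening thresholds and numerical settings, and an output directory.
#' Configurations can be built in code or loaded from a YAML or JSON file
#' with the same field names.
#'
#' @param model_path Path to the parent model (SBML or JSON dialect).
#' @param datasets List of dataset entries, each a list with `id`,
#'   `expression` (TSV path) and `condition` (`"cancer"` or `"control"`).
#' @param drug_path Path to the drug-target TSV, or `NULL` to screen genes
#'   only.
#' @param medium_path Path to the medium TSV, or `NULL` to keep the model's
#'   own exchange bounds.
#' @param out_dir Output directory (created if needed).
#' @param th A [thresholds()] object.
#' @param epsilon Flux activity threshold.
#' @param seed Integer seed recorded in the run log and set before the run.
#' @return A validated `run_config` object.
#' @export
run_config <- function(model_path, datasets, drug_path = NULL,
                       medium_path = NULL, out_dir = "fluxscreen_out",
                       th = thresholds(), epsilon = 1e-4, seed = 1L) {
  cfg <- structure(list(model_path = model_path, datasets = datasets,
                        drug_path = drug_path, medium_path = medium_path,
                        out_dir = out_dir, thresholds = th,
                        epsilon = epsilon, seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  th_args <- raw$thresholds
  th <- if (is.null(th_args)) thresholds() else do.call(thresholds, th_args)
  run_config(model_path = raw$model,
             datasets = lapply(raw$datasets, function(d)
               list(id = d$id, expression = d$expression,
                    condition = d$condition)),
             drug_path = raw$drugs, medium_path = raw$medium,
             out_dir = if (is.null(raw$out_dir)) "fluxscreen_out"
               else raw$out_dir,
             th = th,
             epsilon = if (is.null(raw$epsilon)) 1e-4 else raw$epsilon,
             seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!file.exists(cfg$model_path)) {
    stop("model file not found: ", cfg$model_path, call. = FALSE)
  }
  if (length(cfg$datasets) == 0L) stop("no datasets configured",
                                       call. = FALSE)
  for (d in cfg$datasets) {
    if (is.null(d$id) || is.null(d$expression) || is.null(d$condition)) {
      stop("each dataset needs id, expression and condition", call. = FALSE)
    }
    if (!d$condition %in% c("cancer", "control")) {
      stop(sprintf("dataset '%s': condition must be cancer or control",
                   d$id), call. = FALSE)
    }
    if (!file.exists(d$expression)) {
      stop(sprintf("dataset '%s': expression file not found: %s", d$id,
                   d$expression), call. = FALSE)
    }
  }
  for (p in c(cfg$drug_path, cfg$medium_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("file not found: ", p, call. = FALSE)
    }
  }
  stopifnot(inherits(cfg$thresholds, "thresholds"), cfg$epsilon > 0)
  invisible(cfg)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full screening pipeline
#'
#' Executes read, discretize, flux-consistency, sample-specific and
#' consensus model construction, gene and drug deletion screens, and
#' scoring, writing TSV/JSON reports to the configured output directory.
#' Cancer datasets are screened independently and intersected only at the
#' candidate level; all control datasets together form the safety arm. A
#' drug or gene is a candidate in a dataset when it passes the sample-level
#' rule and, where a consensus model exists, the consensus rule. Without any
#' control dataset the safety filter cannot be applied and reports carry a
#' `no_safety_filter` flag.
#'
#' Outputs (deterministic byte-for-byte for a fixed config): per cancer
#' dataset `report_<id>.tsv` (per-entity scores) and `efficacy_<id>.tsv`
#' (entity x sample growth-ratio matrix), plus `essential_genes.tsv`,
#' `candidates.tsv`, `shared_candidates.tsv`, `enrichment.tsv` and
#' `run_log.json`. Any stage failure aborts with a stage-named error and
#' leaves an `INCOMPLETE` marker in the output directory.
#'
#' @param cfg A [run_config()] (or path to one, which is loaded first).
#' @return Invisibly, a list with the per-dataset reports, the candidate
#'   sets, the intersection, enrichment results and output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(cfg$out_dir, "INCOMPLETE")
  writeLines("pipeline running", marker)
  stage <- "setup"
  result <- tryCatch({
    set.seed(cfg$seed)
    th <- cfg$thresholds
    stage <- "read"
    model <- read_model(cfg$model_path)
    drugs <- if (is.null(cfg$drug_path)) NULL
      else read_drug_table(cfg$drug_path)
    medium <- if (is.null(cfg$medium_path)) NULL
      else read_medium(cfg$medium_path)

    stage <- "discretize"
    datasets <- lapply(cfg$datasets, function(d) {
      expr <- read_expression(d$expression)
      d$calls <- discretize_expression(expr)
      d
    })
    names(datasets) <- vapply(datasets, `[[`, character(1), "id")

    stage <- "build-models"
    for (i in seq_along(datasets)) {
      d <- datasets[[i]]
      datasets[[i]]$contexts <- build_sample_models(
        model, d$calls, medium, d$condition, cfg$epsilon)
      datasets[[i]]$consensus <- build_consensus_model(
        model, d$calls, medium, d$condition,
        th$consensus_activity_fraction, cfg$epsilon, dataset_id = d$id)
    }
    cancer_ids <- names(datasets)[vapply(datasets, `[[`, character(1),
                                         "condition") == "cancer"]
    control_ids <- setdiff(names(datasets), cancer_ids)
    if (length(cancer_ids) == 0L) stop("no cancer dataset configured")
    no_safety <- length(control_ids) == 0L

    stage <- "screen"
    control_contexts <- unlist(lapply(datasets[control_ids], `[[`,
                                      "contexts"), recursive = FALSE)
    control_consensus <- lapply(datasets[control_ids], `[[`, "consensus")
    gene_universe <- sort(model$genes)
    control_sample_out <- if (length(control_contexts))
      screen_dataset(control_contexts, drugs, gene_universe, cfg$epsilon)
      else NULL
    control_cons_out <- if (length(control_consensus))
      screen_dataset(control_consensus, drugs, gene_universe, cfg$epsilon)
      else NULL

    stage <- "score"
    reports <- list()
    candidates <- list()
    gene_candidates <- list()
    paths <- character()
    for (id in cancer_ids) {
      d <- datasets[[id]]
      sample_out <- screen_dataset(d$contexts, drugs, gene_universe,
                                   cfg$epsilon)
      cons_out <- screen_dataset(list(d$consensus), drugs, gene_universe,
                                 cfg$epsilon)
      rep_tab <- screen_report(rbind(sample_out, control_sample_out),
                               rbind(cons_out, control_cons_out), th)
      rep_tab$no_safety_filter <- no_safety
      rep_tab$candidate <- .is_candidate(rep_tab, th, no_safety)
      reports[[id]] <- rep_tab
      candidates[[id]] <- rep_tab$entity_id[rep_tab$candidate &
                                              rep_tab$entity_kind == "drug"]
      gene_candidates[[id]] <- rep_tab$entity_id[rep_tab$candidate &
                                                   rep_tab$entity_kind == "gene"]
      paths <- c(paths, .write_tsv(rep_tab,
        file.path(cfg$out_dir, paste0("report_", id, ".tsv"))))
      eff <- stats::reshape(
        sample_out[sample_out$condition == "cancer",
                   c("entity_id", "context_id", "ratio")],
        idvar = "entity_id", timevar = "context_id", direction = "wide")
      names(eff) <- sub("^ratio\\.", "", names(eff))
      eff <- eff[order(eff$entity_id), ]
      paths <- c(paths, .write_tsv(eff,
        file.path(cfg$out_dir, paste0("efficacy_", id, ".tsv"))))
    }

    stage <- "intersect"
    inter_drugs <- intersect_candidates(candidates)
    inter_genes <- intersect_candidates(gene_candidates)
    ess_tab <- data.frame(gene = rownames(inter_genes$membership),
                          inter_genes$membership,
                          shared = rownames(inter_genes$membership) %in%
                            inter_genes$shared,
                          check.names = FALSE)
    paths <- c(paths, .write_tsv(ess_tab,
      file.path(cfg$out_dir, "essential_genes.tsv")))
    cand_tab <- do.call(rbind, lapply(cancer_ids, function(id) {
      r <- reports[[id]]
      r <- r[r$entity_kind == "drug", ]
      data.frame(dataset = id, drug_id = r$entity_id, score = r$score,
                 nnt = r$nnt, control_harm = r$control_harm,
                 candidate = r$candidate, stringsAsFactors = FALSE)
    }))
    paths <- c(paths, .write_tsv(cand_tab,
      file.path(cfg$out_dir, "candidates.tsv")))
    paths <- c(paths, .write_tsv(
      data.frame(drug_id = inter_drugs$shared),
      file.path(cfg$out_dir, "shared_candidates.tsv")))

    stage <- "enrichment"
    enrich <- NULL
    if (!is.null(drugs)) {
      annotated <- drugs$drug_id[drugs$is_anticancer == 1L]
      enrich <- do.call(rbind, lapply(cancer_ids, function(id) {
        e <- enrichment_score(candidates[[id]], annotated, drugs$drug_id)
        data.frame(dataset = id, predicted = e$n, annotated_hits = e$k,
                   annotated_total = e$K, universe = e$N,
                   p_value = e$p_value, stringsAsFactors = FALSE)
      }))
      enrich$p_adjusted <- stats::p.adjust(enrich$p_value, method = "BH")
      paths <- c(paths, .write_tsv(enrich,
        file.path(cfg$out_dir, "enrichment.tsv")))
    }

    stage <- "log"
    log <- list(package = "fluxscreen",
                version = as.character(utils::packageVersion("fluxscreen")),
                r_version = R.version.string,
                seed = cfg$seed, epsilon = cfg$epsilon,
                thresholds = unclass(th),
                datasets = lapply(datasets, function(d)
                  list(id = d$id, condition = d$condition,
                       n_samples = length(d$contexts),
                       consensus_reactions = length(d$consensus$kept))),
                no_safety_filter = no_safety)
    log_path <- file.path(cfg$out_dir, "run_log.json")
    jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, log_path)
    list(reports = reports, candidates = candidates,
         gene_candidates = gene_candidates, shared_drugs = inter_drugs,
         shared_genes = inter_genes, enrichment = enrich, paths = paths,
         no_safety_filter = no_safety)
  }, error = function(e) {
    writeLines(paste0("failed at stage: ", stage, "\n",
                      conditionMessage(e)), marker)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  unlink(marker)
  invisible(result)
}

# candidate rule: sample-level essential; consensus rule additionally when a
# consensus screen is present; without a control arm only the efficacy side
# of each rule can be applied
.is_candidate <- function(rep_tab, th, no_safety) {
  vapply(seq_len(nrow(rep_tab)), function(i) {
    r <- rep_tab[i, ]
    if (no_safety) {
      ok_samples <- !is.na(r$cancer_efficacy) &&
        r$cancer_efficacy >= th$cancer_sample_fraction_min
      ok_cons <- is.na(r$consensus_cancer_ratio) ||
        r$consensus_cancer_ratio < th$cancer_ratio_max
      return(ok_samples && ok_cons)
    }
    ok_samples <- isTRUE(r$sample_essential)
    ok_cons <- is.na(r$consensus_cancer_ratio) ||
      call_essential_consensus(r$consensus_cancer_ratio,
                               r$consensus_healthy_ratio, th)
    ok_samples && ok_cons
  }, logical(1))
}

#' Write a synthetic fixture to disk as pipeline inputs
#'
#' Materialises [generate_fixture()] as the files [run_pipeline()] consumes
#' (JSON model, expression TSVs for the cancer and control cohorts, drug
#' and medium TSVs) plus a ready-to-run configuration.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Target directory.
#' @param out_dir Output directory recorded in the returned config.
#' @return A [run_config()] pointing at the written files.
#' @export
write_synthetic_inputs <- function(spec, dir,
                                   out_dir = file.path(dir, "out")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- generate_fixture(spec)
  model_path <- file.path(dir, "model.json")
  write_model(fx$model, model_path)
  is_can <- grepl("^CAN", colnames(fx$expression))
  ds <- list()
  if (any(is_can)) {
    expr_cancer <- file.path(dir, "expression_cancer.tsv")
    write_expression(fx$expression[, is_can, drop = FALSE], expr_cancer)
    ds <- c(ds, list(list(id = "SYN", expression = expr_cancer,
                          condition = "cancer")))
  }
  if (any(!is_can)) {
    expr_control <- file.path(dir, "expression_control.tsv")
    write_expression(fx$expression[, !is_can, drop = FALSE], expr_control)
    ds <- c(ds, list(list(id = "SYN-CONTROL", expression = expr_control,
                          condition = "control")))
  }
  drug_path <- file.path(dir, "drugs.tsv")
  write_drug_table(fx$drugs, drug_path)
  medium_path <- file.path(dir, "medium.tsv")
  write_medium(fx$medium, medium_path)
  run_config(model_path = model_path,
             datasets = ds,
             drug_path = drug_path, medium_path = medium_path,
             out_dir = out_dir, seed = spec$seed)
}
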