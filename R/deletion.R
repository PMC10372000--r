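#' Single-gene deletion screen on a context model
#'
#' For each gene of the context model, the reactions whose GPR rule fails
#' without that gene are closed (bounds set to 0) and the objective is
#' re-optimized; the outcome is the growth ratio knockout/wild-type. The
#' wild-type optimum is computed once per context. Ratios are clipped to
#' `[0, 1]` after checking that a knockout never improves the objective
#' beyond numerical tolerance.
#'
#' @param context A `context_model` from [fastcore_extract()] or the model
#'   builders; must be viable for its objective.
#' @param genes Genes to delete; defaults to every gene of the context
#'   model. Genes absent from all GPRs get ratio 1.
#' @param epsilon Activity threshold below which the wild-type objective
#'   marks the context unscreenable.
#' @return Data frame with columns `entity_id`, `entity_kind` (`"gene"`),
#'   `wt_objective`, `ko_objective`, `ratio`, `objective_kind`.
#' @export
single_gene_deletion <- function(context, genes = NULL, epsilon = 1e-4) {
  sc <- .screen_context(context, epsilon)
  if (is.null(genes)) genes <- sort(sc$model$genes)
  rows <- lapply(genes, function(g) {
    .deletion_outcome(sc, g, "gene", g)
  })
  do.call(rbind, rows)
}

#' Simulate a drug as simultaneous knockout of all its targets
#'
#' The drug's target genes are intersected with the model's genes and all
#' mapped targets inactivated at once; reactions whose GPR rules then fail
#' are closed and the objective re-optimized. Multi-target closure is what
#' distinguishes a drug from its single-gene deletions: a drug hitting both
#' members of an isozyme pair can abolish growth even though each single
#' deletion is harmless. A drug with no mapped target gets ratio 1 and
#' `no_target = TRUE`.
#'
#' @param context A viable `context_model`.
#' @param drug_id Drug identifier (reported in the outcome).
#' @param targets Character vector of target gene ids.
#' @param epsilon See [single_gene_deletion()].
#' @return One-row data frame as in [single_gene_deletion()] with
#'   `entity_kind = "drug"` plus a `no_target` flag.
#' @export
drug_deletion <- function(context, drug_id, targets, epsilon = 1e-4) {
  sc <- .screen_context(context, epsilon)
  mapped <- intersect(targets, sc$model$genes)
  out <- .deletion_outcome(sc, mapped, "drug", drug_id)
  out$no_target <- length(mapped) == 0L
  out
}

# resolve and cache the wild-type optimum of a context
.screen_context <- function(context, epsilon) {
  stopifnot(inherits(context, "context_model"))
  if (is.na(context$objective_kind)) {
    stop("context model has no screening objective", call. = FALSE)
  }
  if (!isTRUE(context$viable)) {
    stop(sprintf("context '%s' is not viable for %s; cannot screen",
                 paste(unlist(context$provenance), collapse = ":"),
                 context$objective_kind), call. = FALSE)
  }
  wt <- fba_optimize(context$model, context$objective_kind)$objective_value
  if (wt <= epsilon) {
    stop("wild-type objective at or below epsilon; context unscreenable",
         call. = FALSE)
  }
  list(model = context$model, objective = context$objective_kind, wt = wt)
}

.deletion_outcome <- function(sc, inactive_genes, kind, id, tol = 1e-6) {
  shut <- inactivate_for_genes(sc$model, inactive_genes)
  ko <- if (length(shut) == 0L) sc$wt
    else fba_optimize(sc$model, sc$objective, disabled = shut)$objective_value
  if (ko > sc$wt * (1 + 1e-6) + tol) {
    stop(sprintf("knockout of '%s' improved the objective (%g > %g)",
                 id, ko, sc$wt), call. = FALSE)
  }
  ratio <- min(max(ko / sc$wt, 0), 1)
  data.frame(entity_id = id, entity_kind = kind,
             wt_objective = sc$wt, ko_objective = ko, ratio = ratio,
             objective_kind = sc$objective, stringsAsFactors = FALSE)
}

#' Screen a set of context models against genes and drugs
#'
#' Runs [single_gene_deletion()] and/or [drug_deletion()] on every context,
#' cancer contexts scored on biomass and control contexts on ATP
#' maintenance (each context carries its own objective). Contexts whose
#' wild-type objective is not above `epsilon` are unscreenable: their rows
#' are emitted with `screenable = FALSE` and `NA` ratios so that scoring can
#' exclude them from denominators. Identical contexts (same kept reactions
#' and objective) share one set of LP solves. Output ordering is
#' deterministic: contexts in input order, genes sorted, then drugs in
#' table order.
#'
#' @param contexts List of `context_model`s (typically one per sample).
#' @param drugs Drug table (see [read_drug_table()]) or `NULL`.
#' @param genes `TRUE` to screen all model genes, `FALSE` for none, or a
#'   character vector of gene ids.
#' @param epsilon Activity threshold.
#' @return Data frame with one row per context x entity: `context_id`,
#'   `condition`, `screenable`, plus the outcome columns.
#' @export
screen_dataset <- function(contexts, drugs = NULL, genes = TRUE,
                           epsilon = 1e-4) {
  stopifnot(is.list(contexts))
  tlist <- if (is.null(drugs)) list() else drug_targets(drugs)
  # one gene universe across all contexts so entities align between arms;
  # genes absent from a given context get ratio 1 there
  gene_set <- if (isTRUE(genes)) {
    sort(unique(unlist(lapply(contexts, function(ctx) ctx$model$genes))))
  } else if (is.character(genes)) genes else character()
  cache <- new.env(parent = emptyenv())
  rows <- lapply(contexts, function(ctx) {
    cid <- as.character(ctx$provenance$id)
    condition <- if (identical(ctx$objective_kind, "biomass")) "cancer"
      else "control"
    screenable <- isTRUE(ctx$viable) &&
      ctx$objective_value > epsilon
    if (!screenable) {
      ids <- c(gene_set, names(tlist))
      kinds <- c(rep("gene", length(gene_set)), rep("drug", length(tlist)))
      if (length(ids) == 0L) return(NULL)
      return(data.frame(context_id = cid, condition = condition,
                        screenable = FALSE, entity_id = ids,
                        entity_kind = kinds, wt_objective = NA_real_,
                        ko_objective = NA_real_, ratio = NA_real_,
                        objective_kind = ctx$objective_kind,
                        no_target = NA, stringsAsFactors = FALSE))
    }
    key <- paste0("ctx:", ctx$objective_kind, ":",
                  paste(ctx$kept, collapse = "\r"))
    if (exists(key, envir = cache, inherits = FALSE)) {
      res <- get(key, cache)
    } else {
      gout <- if (length(gene_set))
        single_gene_deletion(ctx, gene_set, epsilon) else NULL
      if (!is.null(gout)) gout$no_target <- FALSE
      dout <- if (length(tlist)) do.call(rbind, lapply(names(tlist),
        function(d) drug_deletion(ctx, d, tlist[[d]], epsilon))) else NULL
      res <- rbind(gout, dout)
      cache[[key]] <- res
    }
    if (is.null(res)) return(NULL)
    cbind(data.frame(context_id = cid, condition = condition,
                     screenable = TRUE, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
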