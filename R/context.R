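#' Discretize an expression matrix into ternary calls
#'
#' Per sample, a two-component Gaussian mixture is fitted to the
#' `log2(value + 1)` of the nonzero entries (via \pkg{mclust}). The two
#' component means anchor a pair of cuts placed at fractions `zone[1]` and
#' `zone[2]` of the way from the lower to the upper mean: values at or above
#' the upper cut are called expressed (boundary inclusive upward), values
#' below the lower cut not expressed, values in between unknown. Zeros are
#' always not expressed. Setting `zone = c(0, 1)` makes the component means
#' themselves the zone boundaries.
#'
#' A degenerate sample -- too few distinct nonzero values, a failed fit, or
#' component means closer than `sep_floor` -- falls back to a single global
#' percentile cut over the whole matrix, with a warning.
#'
#' @param mat Nonnegative numeric matrix, genes x samples.
#' @param zone Two increasing fractions in `[0, 1]` placing the
#'   not-expressed and expressed cuts between the component means.
#' @param sep_floor Minimal separation (log2 units) between component means
#'   for the mixture to count as bimodal.
#' @param fallback_quantile Quantile of the pooled nonzero `log2(x + 1)`
#'   values used as the single cut when a sample is degenerate.
#' @return Integer matrix of the same shape: 1 expressed, -1 not expressed,
#'   0 unknown.
#' @importFrom mclust Mclust mclustBIC
#' @export
discretize_expression <- function(mat, zone = c(0.4, 0.6), sep_floor = 1,
                                  fallback_quantile = 0.5) {
  stopifnot(is.matrix(mat), all(mat >= 0, na.rm = TRUE),
            length(zone) == 2L, zone[1] <= zone[2])
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat))) {
    stop("samples must have unique names", call. = FALSE)
  }
  calls <- matrix(-1L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  lmat <- log2(mat + 1)
  global_cut <- NULL
  degenerate <- character()
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    lx <- lmat[, j]
    nz <- lx[x > 0]
    mu <- NULL
    if (length(unique(round(nz, 8))) >= 5L) {
      fit <- tryCatch(
        Mclust(nz, G = 2, verbose = FALSE),
        error = function(e) NULL)
      if (!is.null(fit) && length(fit$parameters$mean) == 2L) {
        mu <- sort(as.numeric(fit$parameters$mean))
      }
    }
    if (is.null(mu) || diff(mu) < sep_floor) {
      degenerate <- c(degenerate, colnames(mat)[j])
      if (is.null(global_cut)) {
        pooled <- lmat[mat > 0]
        global_cut <- stats::quantile(pooled, fallback_quantile, names = FALSE)
      }
      calls[, j] <- ifelse(x == 0, -1L, ifelse(lx >= global_cut, 1L, -1L))
      next
    }
    lo_cut <- mu[1] + zone[1] * diff(mu)
    hi_cut <- mu[1] + zone[2] * diff(mu)
    cj <- integer(nrow(mat))
    cj[lx >= hi_cut] <- 1L
    cj[lx < lo_cut] <- -1L
    cj[x == 0] <- -1L
    calls[, j] <- cj
  }
  if (length(degenerate)) {
    warning("degenerate expression distribution; used global percentile cut ",
            "for sample(s): ", paste(degenerate, collapse = ", "),
            call. = FALSE)
  }
  calls
}

#' Core reaction set of one sample
#'
#' A reaction is core iff it has a GPR and the rule evaluates to `TRUE`
#' under the substitution expressed -> active, not expressed or unknown ->
#' inactive (the conservative reading of the unknown zone). Reactions
#' without a GPR (transports, spontaneous) are never core; they remain in
#' the parent network as scaffold that the extraction may add back.
#'
#' @param model A [metabolic_model].
#' @param calls Ternary call matrix from [discretize_expression()].
#' @param sample Sample (column) name.
#' @return Character vector of core reaction ids.
#' @export
reaction_core_from_calls <- function(model, calls, sample) {
  if (!sample %in% colnames(calls)) {
    stop("unknown sample: ", sample, call. = FALSE)
  }
  expressed <- rownames(calls)[calls[, sample] == 1L]
  inactive <- setdiff(model$genes, expressed)
  core <- vapply(model$rxns, function(rid) {
    g <- model$gpr[[rid]]
    !is.null(g) && evaluate_gpr(g, inactive)
  }, logical(1))
  model$rxns[core]
}

# shared preamble: medium, consistency, objective availability
.context_parent <- function(model, medium, condition, epsilon) {
  condition <- match.arg(condition, c("cancer", "control"))
  objective <- if (condition == "cancer") "biomass" else "atp_maintenance"
  m <- if (!is.null(medium)) apply_medium(model, medium) else model
  consistent <- fastcc(m, epsilon)
  mc <- subset_model(m, consistent)
  obj_rid <- switch(objective, biomass = model$biomass,
                    atp_maintenance = model$atp_maintenance)
  if (is.na(obj_rid) || !obj_rid %in% mc$rxns) {
    stop(sprintf(
      "objective '%s' is absent or blocked under this medium; cannot build %s models",
      objective, condition), call. = FALSE)
  }
  list(mc = mc, objective = objective)
}

#' Build sample-specific context models
#'
#' For each sample: derive the core reaction set from its expression calls,
#' append the condition's objective (biomass for cancer, ATP maintenance for
#' control), and extract a flux-consistent context model with FASTCORE.
#' The parent model is first constrained to the medium and reduced to its
#' flux-consistent part, so expression evidence on blocked reactions is
#' ignored rather than fatal. Samples with identical cores share one
#' extraction (the result is cached), keeping large cohorts cheap.
#'
#' @param model A [metabolic_model] (the generic parent reconstruction).
#' @param calls Ternary call matrix from [discretize_expression()].
#' @param medium Optional named uptake vector, see [apply_medium()].
#' @param condition `"cancer"` (screened on biomass) or `"control"`
#'   (screened on ATP maintenance).
#' @param epsilon Flux activity threshold.
#' @return Named list of `context_model`s, one per sample (column) of
#'   `calls`.
#' @export
build_sample_models <- function(model, calls, medium = NULL,
                                condition = c("cancer", "control"),
                                epsilon = 1e-4) {
  condition <- match.arg(condition)
  parent <- .context_parent(model, medium, condition, epsilon)
  cache <- new.env(parent = emptyenv())
  out <- lapply(colnames(calls), function(s) {
    core <- reaction_core_from_calls(parent$mc, calls, s)
    key <- paste0("core:", paste(core, collapse = "\r"))
    ctx <- if (exists(key, envir = cache, inherits = FALSE)) get(key, cache)
      else (cache[[key]] <- fastcore_extract(
        parent$mc, core, epsilon, objective = parent$objective,
        provenance = list(kind = "sample_specific", id = s)))
    ctx$provenance <- list(kind = "sample_specific", id = s)
    ctx
  })
  names(out) <- colnames(calls)
  out
}

#' Build a consensus context model
#'
#' The consensus core contains the reactions that are core in at least
#' `activity_fraction` of the samples (boundary inclusive: with 10 samples
#' and the default 0.9, core-in-9 qualifies); the condition's objective is
#' then appended and FASTCORE extracts the consensus model.
#'
#' @inheritParams build_sample_models
#' @param activity_fraction Minimal fraction of samples in which a reaction
#'   must be core; default 0.9.
#' @param dataset_id Provenance label for the consensus model.
#' @return A `context_model`.
#' @export
build_consensus_model <- function(model, calls, medium = NULL,
                                  condition = c("cancer", "control"),
                                  activity_fraction = 0.9, epsilon = 1e-4,
                                  dataset_id = "consensus") {
  condition <- match.arg(condition)
  stopifnot(activity_fraction >= 0, activity_fraction <= 1)
  if (ncol(calls) < 1L) stop("need at least one sample", call. = FALSE)
  parent <- .context_parent(model, medium, condition, epsilon)
  n_core <- integer(length(parent$mc$rxns))
  names(n_core) <- parent$mc$rxns
  for (s in colnames(calls)) {
    core <- reaction_core_from_calls(parent$mc, calls, s)
    n_core[core] <- n_core[core] + 1L
  }
  consensus_core <- names(n_core)[n_core / ncol(calls) >= activity_fraction]
  fastcore_extract(parent$mc, consensus_core, epsilon,
                   objective = parent$objective,
                   provenance = list(kind = "consensus", id = dataset_id))
}
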