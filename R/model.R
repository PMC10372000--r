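#' Construct a metabolic network model
#'
#' A `metabolic_model` holds a stoichiometric matrix, flux bounds, GPR rules
#' and the named screening objectives (a biomass drain for growth and an
#' ATP-maintenance drain for the energy balance of non-growing cells).
#' Fluxes are in nominal mmol/gDW/h; stoichiometric coefficients are signed
#' and dimensionless. Exchange reactions touch exactly one metabolite and
#' follow the standard sign convention: positive flux is secretion, negative
#' flux is uptake.
#'
#' @param model_id Model identifier.
#' @param metabolites Character vector of metabolite ids (compartment tags may
#'   be embedded in the id, e.g. `"glc[e]"`).
#' @param reactions List of reactions, each a list with elements `id`,
#'   `stoich` (named numeric: metabolite id -> coefficient), `lb`, `ub`, and
#'   optionally `gpr` (rule string or parsed tree).
#' @param genes Optional character vector of gene ids; defaults to the union
#'   of genes used in GPRs. Every gene used in a GPR must be listed.
#' @param biomass,atp_maintenance Reaction ids of the two screening
#'   objectives, or `NA` if absent.
#' @return An object of class `metabolic_model` with fields `id`, `mets`,
#'   `rxns`, `S` (metabolites x reactions), `lb`, `ub`, `gpr` (named list of
#'   trees), `genes`, `biomass`, `atp_maintenance`, `exchanges`.
#' @export
metabolic_model <- function(model_id, metabolites, reactions, genes = NULL,
                            biomass = NA_character_,
                            atp_maintenance = NA_character_) {
  stopifnot(is.character(metabolites), is.list(reactions))
  if (anyDuplicated(metabolites)) {
    stop("duplicated metabolite ids: ",
         paste(unique(metabolites[duplicated(metabolites)]), collapse = ", "),
         call. = FALSE)
  }
  rxn_ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rxn_ids)) {
    stop("duplicated reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(rxn_ids)
  S <- matrix(0, nrow = length(metabolites), ncol = n,
              dimnames = list(metabolites, rxn_ids))
  lb <- ub <- numeric(n)
  gpr <- vector("list", n)
  names(gpr) <- rxn_ids
  for (k in seq_len(n)) {
    r <- reactions[[k]]
    st <- r$stoich
    if (length(st)) {
      bad <- setdiff(names(st), metabolites)
      if (length(bad)) {
        stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                     rxn_ids[k], paste(bad, collapse = ", ")), call. = FALSE)
      }
      S[names(st), k] <- as.numeric(st)
    }
    lb[k] <- as.numeric(r$lb)
    ub[k] <- as.numeric(r$ub)
    if (lb[k] > ub[k]) {
      stop(sprintf("reaction '%s' has lower bound %g > upper bound %g",
                   rxn_ids[k], lb[k], ub[k]), call. = FALSE)
    }
    g <- r$gpr
    if (is.character(g)) g <- parse_gpr(g)  # "" parses to the empty rule
    if (!is.null(g)) {  # NULL assignment would delete the list slot
      gpr[[k]] <- g
    }
  }
  names(lb) <- names(ub) <- rxn_ids
  used_genes <- unique(unlist(lapply(gpr, gpr_genes)))
  if (is.null(genes)) {
    genes <- sort(used_genes)
  } else {
    missing <- setdiff(used_genes, genes)
    if (length(missing)) {
      stop("GPR rules reference undeclared gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  for (obj in c(biomass = biomass, atp_maintenance = atp_maintenance)) {
    if (!is.na(obj) && !obj %in% rxn_ids) {
      stop(sprintf("objective reaction '%s' is not a declared reaction", obj),
           call. = FALSE)
    }
  }
  # exchange reactions: stoichiometry touches exactly one metabolite
  n_mets_touched <- colSums(S != 0)
  exchanges <- rxn_ids[n_mets_touched == 1L]
  structure(
    list(id = as.character(model_id), mets = metabolites, rxns = rxn_ids,
         S = S, lb = lb, ub = ub, gpr = gpr, genes = as.character(genes),
         biomass = biomass, atp_maintenance = atp_maintenance,
         exchanges = exchanges),
    class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s'>\n", x$id))
  cat(sprintf("  %d metabolites, %d reactions (%d exchanges), %d genes\n",
              length(x$mets), length(x$rxns), length(x$exchanges),
              length(x$genes)))
  cat(sprintf("  biomass: %s   atp_maintenance: %s\n",
              ifelse(is.na(x$biomass), "<none>", x$biomass),
              ifelse(is.na(x$atp_maintenance), "<none>", x$atp_maintenance)))
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  rev <- sum(object$lb < 0 & !(object$rxns %in% object$exchanges))
  with_gpr <- sum(!vapply(object$gpr, is.null, logical(1)))
  cat(sprintf("Model '%s': %d reactions (%d reversible internal, %d with GPR),",
              object$id, length(object$rxns), rev, with_gpr), "\n")
  cat(sprintf("  %d metabolites, %d genes, %d exchange reactions\n",
              length(object$mets), length(object$genes),
              length(object$exchanges)))
  invisible(object)
}

# resolve "biomass"/"atp_maintenance" or a literal reaction id
.resolve_objective <- function(model, objective) {
  stopifnot(length(objective) == 1L)
  rid <- switch(objective,
                biomass = model$biomass,
                atp_maintenance = model$atp_maintenance,
                objective)
  if (is.na(rid) || !rid %in% model$rxns) {
    stop(sprintf("objective '%s' does not name a reaction in model '%s'",
                 objective, model$id), call. = FALSE)
  }
  rid
}

#' Restrict a model to a subset of its reactions
#'
#' Keeps the named reactions and the metabolites they touch; genes are pruned
#' to those appearing in a kept GPR. Objective reactions that are dropped
#' become `NA` in the submodel.
#'
#' @param model A [metabolic_model].
#' @param keep Character vector of reaction ids to retain.
#' @return A [metabolic_model].
#' @export
subset_model <- function(model, keep) {
  bad <- setdiff(keep, model$rxns)
  if (length(bad)) {
    stop("unknown reaction id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- model$rxns[model$rxns %in% keep]  # preserve model order
  S <- model$S[, keep, drop = FALSE]
  used_mets <- model$mets[rowSums(S != 0) > 0]
  reactions <- lapply(keep, function(rid) {
    st <- model$S[, rid]
    st <- st[st != 0]
    list(id = rid, stoich = st, lb = model$lb[[rid]], ub = model$ub[[rid]],
         gpr = model$gpr[[rid]])
  })
  metabolic_model(
    model_id = model$id,
    metabolites = used_mets,
    reactions = reactions,
    biomass = if (!is.na(model$biomass) && model$biomass %in% keep)
      model$biomass else NA_character_,
    atp_maintenance = if (!is.na(model$atp_maintenance) &&
                          model$atp_maintenance %in% keep)
      model$atp_maintenance else NA_character_)
}

#' Reactions inactivated by a gene knockout
#'
#' Applies the GPR rules: a reaction is shut iff its rule evaluates to
#' `FALSE` with the given genes inactive. Reactions without a GPR are never
#' shut. Gene ids absent from the model are ignored. The model is not
#' modified; deletion is simulated downstream by closing the returned
#' reactions' bounds.
#'
#' @param model A [metabolic_model].
#' @param inactive_genes Character vector of knocked-out gene ids.
#' @return Character vector of reaction ids to disable.
#' @export
inactivate_for_genes <- function(model, inactive_genes) {
  inactive_genes <- intersect(inactive_genes, model$genes)
  if (length(inactive_genes) == 0L) return(character())
  dead <- vapply(model$rxns, function(rid) {
    g <- model$gpr[[rid]]
    !is.null(g) && !evaluate_gpr(g, inactive_genes)
  }, logical(1))
  model$rxns[dead]
}
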