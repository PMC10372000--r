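# FASTCORE-family context extraction.
#
# Given a flux-consistent parent network and a set of core reactions that
# expression evidence requires to be active, FASTCORE finds a small
# flux-consistent subnetwork containing every core reaction by alternating
# two LPs: LP7 pushes pending core reactions above the activity threshold,
# LP10 reproduces that activity while minimising the L1 support of non-core
# reactions. Reversible pending reactions are tried in both orientations;
# a core reaction supportable in neither is reported as blocked.

# LP10: minimise sum over P of |v_p| subject to S v = 0, v_k >= epsilon for
# k in K, bounds. Variables [v, w_P] with -w_p <= v_p <= w_p.
.lp10 <- function(S, lb, ub, K, P, epsilon) {
  n <- ncol(S)
  lb2 <- lb
  lb2[K] <- pmax(lb2[K], epsilon)
  if (length(P) == 0L) {
    sol <- .solve_lp(rep(0, n), lb2, ub, Aeq = S, beq = rep(0, nrow(S)),
                     maximize = FALSE)
    return(if (sol$status == "optimal") sol$x else NULL)
  }
  k <- length(P)
  big <- max(abs(c(lb, ub)), 1)
  obj <- c(rep(0, n), rep(1, k))
  lbw <- c(lb2, rep(0, k))
  ubw <- c(ub, rep(big, k))
  Aeq <- cbind(S, matrix(0, nrow(S), k))
  Aineq <- matrix(0, 2L * k, n + k)
  Aineq[cbind(seq_len(k), P)] <- 1          #  v_p - w_p <= 0
  Aineq[cbind(seq_len(k), n + seq_len(k))] <- -1
  Aineq[cbind(k + seq_len(k), P)] <- -1     # -v_p - w_p <= 0
  Aineq[cbind(k + seq_len(k), n + seq_len(k))] <- -1
  sol <- .solve_lp(obj, lbw, ubw, Aeq = Aeq, beq = rep(0, nrow(S)),
                   Aineq = Aineq, bineq = rep(0, 2L * k), maximize = FALSE)
  if (sol$status != "optimal") return(NULL)
  sol$x[seq_len(n)]
}

.find_sparse_mode <- function(S, lb, ub, J, P, singleton, epsilon) {
  if (length(J) == 0L) return(integer())
  Ji <- if (singleton) J[1L] else J
  v <- .lp7(S, lb, ub, Ji, epsilon)
  K <- Ji[v[Ji] >= 0.99 * epsilon]
  if (length(K) == 0L) return(integer())
  # LP10 pins the found core members a full epsilon above zero, leaving
  # headroom over the 0.99*epsilon support cut
  v <- .lp10(S, lb, ub, K, P, epsilon)
  if (is.null(v)) return(integer())
  which(abs(v) >= 0.99 * epsilon)
}

# core algorithm on indices; assumes the input network is flux-consistent
.fastcore_set <- function(S, lb, ub, core, epsilon, rxn_ids) {
  n <- ncol(S)
  irr <- lb >= 0
  flipped <- FALSE
  singleton <- FALSE
  J <- intersect(core, which(irr))
  P <- setdiff(seq_len(n), core)
  supp <- .find_sparse_mode(S, lb, ub, J, P, FALSE, epsilon)
  if (!all(J %in% supp)) {
    stop("blocked core reaction(s): ",
         paste(rxn_ids[setdiff(J, supp)], collapse = ", "), call. = FALSE)
  }
  A <- supp
  J <- setdiff(core, A)
  while (length(J)) {
    P <- setdiff(P, A)
    supp <- .find_sparse_mode(S, lb, ub, J, P, singleton, epsilon)
    A <- union(A, supp)
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      Ji_rev <- setdiff(if (singleton) J[1L] else J, which(irr))
      if (flipped || length(Ji_rev) == 0L) {
        if (singleton) {
          stop("blocked core reaction(s): ",
               paste(rxn_ids[J], collapse = ", "), call. = FALSE)
        }
        flipped <- FALSE
        singleton <- TRUE
      } else {
        # reorient reversible pending-core reactions
        S[, Ji_rev] <- -S[, Ji_rev, drop = FALSE]
        tmp <- lb[Ji_rev]
        lb[Ji_rev] <- -ub[Ji_rev]
        ub[Ji_rev] <- -tmp
        flipped <- TRUE
      }
    }
  }
  sort(A)
}

#' Extract a context-specific model around a core reaction set
#'
#' Runs FASTCORE on a flux-consistent parent model: the result is a
#' flux-consistent subnetwork that contains every core reaction plus a small
#' set of supporting reactions. When an objective kind is supplied, the
#' objective reaction is appended to the core before extraction (a screened
#' model must support its objective), and the extracted model is flagged
#' viable iff the objective optimum exceeds `epsilon`.
#'
#' The parent model must itself be flux-consistent (run [fastcc()] and
#' [subset_model()] first); a core reaction that cannot carry flux in the
#' parent raises an error naming the blocked reactions.
#'
#' @param model A flux-consistent [metabolic_model].
#' @param core Character vector of core reaction ids.
#' @param epsilon Flux activity threshold; default `1e-4`.
#' @param objective `NULL`, `"biomass"` or `"atp_maintenance"`.
#' @param provenance List describing how the context was derived, e.g.
#'   `list(kind = "sample_specific", id = "S01")`.
#' @return A `context_model`: list with `parent_id`, `kept` (reaction ids),
#'   `model` (the extracted [metabolic_model]), `provenance`,
#'   `objective_kind`, `objective_value`, `viable`.
#' @export
fastcore_extract <- function(model, core, epsilon = 1e-4, objective = NULL,
                             provenance = list(kind = "ad_hoc", id = NA)) {
  bad <- setdiff(core, model$rxns)
  if (length(bad)) {
    stop("core contains unknown reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  obj_rid <- NULL
  if (!is.null(objective)) {
    obj_rid <- .resolve_objective(model, objective)
    core <- union(core, obj_rid)
  }
  if (length(core) == 0L) {
    kept <- character()
  } else {
    idx <- .fastcore_set(model$S, unname(model$lb), unname(model$ub),
                         match(core, model$rxns), epsilon, model$rxns)
    kept <- model$rxns[idx]
  }
  sub <- subset_model(model, kept)
  objective_value <- NA_real_
  viable <- NA
  if (!is.null(objective)) {
    if (obj_rid %in% kept) {
      objective_value <- fba_optimize(sub, objective)$objective_value
      viable <- objective_value > epsilon
    } else {
      objective_value <- 0
      viable <- FALSE
    }
  }
  structure(list(parent_id = model$id, kept = kept, model = sub,
                 provenance = provenance,
                 objective_kind = if (is.null(objective)) NA_character_
                   else objective,
                 objective_value = objective_value, viable = viable),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  prov <- paste(unlist(x$provenance), collapse = ":")
  cat(sprintf("<context_model of '%s' [%s]> %d reactions kept",
              x$parent_id, prov, length(x$kept)))
  if (!is.na(x$objective_kind)) {
    cat(sprintf("; %s = %.4g (%s)", x$objective_kind, x$objective_value,
                if (isTRUE(x$viable)) "viable" else "non-viable"))
  }
  cat("\n")
  invisible(x)
}
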