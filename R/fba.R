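#' Flux balance analysis
#'
#' Maximizes the flux through an objective reaction subject to steady-state
#' mass balance (`S v = 0`) and the model's flux bounds, optionally with a
#' set of reactions disabled (bounds closed to `[0, 0]`, the in silico
#' knockout operation). An infeasible problem is reported with objective
#' value 0: a knockout that destroys feasibility also destroys growth, and
#' downstream growth ratios need a number.
#'
#' @param model A [metabolic_model].
#' @param objective `"biomass"`, `"atp_maintenance"`, or a reaction id.
#' @param disabled Character vector of reaction ids to close.
#' @param feas_tol Feasibility tolerance for the mass-balance check on the
#'   returned solution.
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"`), `objective_value`, and `fluxes` (named numeric).
#' @examples
#' m <- example_chain_model()
#' fba_optimize(m, "biomass")$objective_value        # 10: uptake-limited
#' fba_optimize(m, "biomass", disabled = "R1")$objective_value  # 0
#' @export
fba_optimize <- function(model, objective = "biomass",
                         disabled = character(), feas_tol = 1e-7) {
  rid <- .resolve_objective(model, objective)
  bad <- setdiff(disabled, model$rxns)
  if (length(bad)) {
    stop("cannot disable unknown reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lb <- model$lb
  ub <- model$ub
  lb[disabled] <- 0
  ub[disabled] <- 0
  obj <- as.numeric(model$rxns == rid)
  sol <- .solve_lp(obj, lb = lb, ub = ub, Aeq = model$S,
                   beq = rep(0, nrow(model$S)), maximize = TRUE)
  if (sol$status == "maxiter") {
    stop("LP failed to converge for model '", model$id, "'", call. = FALSE)
  }
  fluxes <- sol$x
  names(fluxes) <- model$rxns
  obj_val <- if (sol$status == "optimal") sol$objective else 0
  if (sol$status == "optimal") {
    resid <- max(abs(model$S %*% fluxes))
    if (resid > feas_tol) {
      stop(sprintf("mass-balance residual %.3g exceeds tolerance %.3g",
                   resid, feas_tol), call. = FALSE)
    }
  }
  structure(list(status = sol$status, objective_value = obj_val,
                 objective_reaction = rid, fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s, objective %s = %.6g\n", x$status,
              x$objective_reaction, x$objective_value))
  invisible(x)
}

#' Constrain a model to a growth medium
#'
#' Exchange reactions follow the secretion-positive sign convention, so
#' uptake of a metabolite runs at negative flux. Metabolites listed in the
#' medium get their maximal uptake set to the stated value; exchangeable
#' metabolites absent from the medium have uptake closed (lower bound
#' clamped to at least 0). Secretion bounds are untouched. Medium entries
#' that match no exchange reaction raise a warning, not an error.
#'
#' @param model A [metabolic_model].
#' @param medium Named numeric vector: metabolite id -> maximal uptake flux
#'   (nonnegative, mmol/gDW/h).
#' @return The constrained [metabolic_model].
#' @export
apply_medium <- function(model, medium) {
  stopifnot(is.numeric(medium), !is.null(names(medium)))
  if (any(medium < 0)) stop("uptake bounds must be nonnegative", call. = FALSE)
  # metabolite consumed by each exchange reaction
  ex_met <- vapply(model$exchanges, function(rid) {
    st <- model$S[, rid]
    model$mets[st != 0]
  }, character(1))
  unmatched <- setdiff(names(medium), ex_met)
  if (length(unmatched)) {
    warning("medium metabolite(s) with no exchange reaction: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(model$exchanges)) {
    rid <- model$exchanges[i]
    met <- ex_met[[i]]
    coef <- model$S[met, rid]
    if (coef < 0) {  # secretion-positive orientation: uptake at v < 0
      if (met %in% names(medium)) {
        model$lb[[rid]] <- -medium[[met]]
      } else {
        model$lb[[rid]] <- max(model$lb[[rid]], 0)
      }
    } else {         # import-positive orientation: uptake at v > 0
      if (met %in% names(medium)) {
        model$ub[[rid]] <- medium[[met]]
      } else {
        model$ub[[rid]] <- min(model$ub[[rid]], 0)
      }
    }
  }
  model
}

# LP7 of the FASTCORE family: push as many reactions in J as possible to a
# forward flux >= epsilon. Variables are [v, z_J]; maximize sum(z) with
# 0 <= z_j <= epsilon and z_j <= v_j.
.lp7 <- function(S, lb, ub, J, epsilon) {
  n <- ncol(S)
  k <- length(J)
  if (k == 0L) return(rep(0, n))
  obj <- c(rep(0, n), rep(1, k))
  lb2 <- c(lb, rep(0, k))
  ub2 <- c(ub, rep(epsilon, k))
  Aeq <- cbind(S, matrix(0, nrow(S), k))
  # z_j - v_j <= 0
  Aineq <- matrix(0, k, n + k)
  Aineq[cbind(seq_len(k), J)] <- -1
  Aineq[cbind(seq_len(k), n + seq_len(k))] <- 1
  sol <- .solve_lp(obj, lb2, ub2, Aeq = Aeq, beq = rep(0, nrow(S)),
                   Aineq = Aineq, bineq = rep(0, k), maximize = TRUE)
  if (sol$status != "optimal") return(rep(0, n))
  sol$x[seq_len(n)]
}

#' Flux-consistency test (FASTCC)
#'
#' Finds the reactions that can carry a flux of magnitude at least `epsilon`
#' in some steady-state solution, using the FASTCC iterative LP scheme:
#' jointly push sets of candidate reactions above `epsilon` (LP7), flip the
#' orientation of unsupported reversible candidates, and drop candidates
#' that remain unsupportable. Reactions outside the returned set are blocked
#' (dead ends, orphans, or bound-closed).
#'
#' @param model A [metabolic_model].
#' @param epsilon Flux activity threshold (> 0); default `1e-4` in model
#'   flux units.
#' @return Character vector of flux-consistent reaction ids (in model order).
#' @export
fastcc <- function(model, epsilon = 1e-4) {
  stopifnot(epsilon > 0)
  S <- model$S
  lb <- unname(model$lb)
  ub <- unname(model$ub)
  n <- ncol(S)
  tol <- 0.99 * epsilon
  irr <- which(lb >= 0)
  supp_of <- function(v) which(abs(v) >= tol)

  A <- integer()
  J <- irr
  v <- .lp7(S, lb, ub, J, epsilon)
  A <- union(A, supp_of(v))
  inconsistent_irr <- setdiff(J, A)
  J <- setdiff(setdiff(seq_len(n), A), inconsistent_irr)

  flipped <- FALSE
  singleton <- FALSE
  while (length(J)) {
    Ji <- if (singleton) J[1L] else J
    v <- .lp7(S, lb, ub, Ji, epsilon)
    A <- union(A, supp_of(v))
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      Ji_rev <- setdiff(Ji, irr)
      if (flipped || length(Ji_rev) == 0L) {
        flipped <- FALSE
        if (singleton) {
          J <- setdiff(J, Ji)  # irrecoverably blocked
        } else {
          singleton <- TRUE
        }
      } else {
        # reorient reversible candidates: negate the column, swap bounds
        S[, Ji_rev] <- -S[, Ji_rev, drop = FALSE]
        tmp <- lb[Ji_rev]
        lb[Ji_rev] <- -ub[Ji_rev]
        ub[Ji_rev] <- -tmp
        flipped <- TRUE
      }
    }
  }
  model$rxns[sort(A)]
}
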