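# Internal linear-programming layer.
#
# All flux problems in this package are small dense LPs of the form
#     max/min  c'x   s.t.  Aeq x = beq,  Aineq x <= bineq,  lb <= x <= ub
# They are solved by a two-phase bounded-variable primal simplex implemented
# below. FBA systems are highly degenerate (the steady-state right-hand side
# is zero), so the implementation uses Bland's anti-cycling rule throughout
# and treats bound flips of nonbasic variables as first-class ratio-test
# outcomes.

# Phase-driven bounded simplex on the equality form A x = b with bounds.
# `l`/`u` may be infinite (slacks). Returns list(status, x).
.bounded_simplex <- function(cc, A, b, l, u, maximize = TRUE, tol = 1e-9) {
  if (!maximize) cc <- -cc
  m <- nrow(A)
  n <- ncol(A)
  # initial nonbasic values at a finite bound (prefer lower)
  init_val <- ifelse(is.finite(l), l, ifelse(is.finite(u), u, 0))
  # phase 1: artificial variable per row, flipped so artificials start >= 0
  resid <- b - as.vector(A %*% init_val)
  sgn <- ifelse(resid < 0, -1, 1)
  A1 <- cbind(A * sgn, diag(m))
  b1 <- b * sgn
  l1 <- c(l, rep(0, m))
  u1 <- c(u, rep(Inf, m))
  c1 <- c(rep(0, n), rep(-1, m))
  at_upper <- !is.finite(l) & is.finite(u)
  st <- .simplex_iterate(c1, A1, b1, l1, u1,
                         basis = n + seq_len(m),
                         at_upper = c(at_upper, rep(FALSE, m)), tol = tol)
  if (st$status != "optimal") return(list(status = st$status, x = NULL))
  art_val <- sum(abs(st$x[n + seq_len(m)]))
  if (art_val > 1e-7) return(list(status = "infeasible", x = NULL))
  # phase 2: freeze artificials at 0 and optimize the real objective
  u1[n + seq_len(m)] <- 0
  l1[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  st <- .simplex_iterate(c2, A1, b1, l1, u1, basis = st$basis,
                         at_upper = st$at_upper, tol = tol)
  if (st$status != "optimal") return(list(status = st$status, x = NULL))
  list(status = "optimal", x = st$x[seq_len(n)])
}

# primal simplex iterations (maximization) from a given basis;
# nonbasic variables sit at lower (default) or upper bound per `at_upper`
.simplex_iterate <- function(cc, A, b, l, u, basis, at_upper, tol = 1e-9,
                             max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  in_basis <- logical(n)
  in_basis[basis] <- TRUE
  xval <- ifelse(at_upper, u, ifelse(is.finite(l), l, 0))
  for (iter in seq_len(max_iter)) {
    nb <- which(!in_basis)
    B <- A[, basis, drop = FALSE]
    xN <- xval[nb]
    rhs <- b - as.vector(A[, nb, drop = FALSE] %*% xN)
    Binv_available <- TRUE
    xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(xB)) return(list(status = "singular", x = NULL))
    xval[basis] <- xB
    y <- solve(t(B), cc[basis])
    rc <- cc[nb] - as.vector(crossprod(A[, nb, drop = FALSE], y))
    improving <- (rc > tol & !at_upper[nb]) | (rc < -tol & at_upper[nb])
    if (!any(improving)) {
      return(list(status = "optimal", x = xval, basis = basis,
                  at_upper = at_upper))
    }
    q <- nb[improving][which.min(nb[improving])]  # Bland: smallest index
    dirsgn <- if (at_upper[q]) -1 else 1          # x_q moves off its bound
    d <- solve(B, A[, q]) * dirsgn
    # ratio test: basic vars stay within bounds; x_q may flip to other bound
    t_max <- if (is.finite(u[q]) && is.finite(l[q])) u[q] - l[q] else Inf
    leave <- 0L
    for (i in seq_len(m)) {
      if (d[i] > tol) {
        ti <- (xB[i] - l[basis[i]]) / d[i]
      } else if (d[i] < -tol) {
        ti <- (xB[i] - u[basis[i]]) / d[i]
      } else next
      if (is.na(ti)) next  # Inf - Inf: unbounded basic in that direction
      slack <- if (is.finite(t_max)) tol * max(1, abs(t_max)) else 0
      if (ti < t_max - slack) {
        t_max <- ti
        leave <- i
      } else if (leave != 0L && is.finite(t_max) &&
                 abs(ti - t_max) <= tol * max(1, abs(t_max)) &&
                 basis[i] < basis[leave]) {
        leave <- i  # Bland tie-break on the leaving variable
      }
    }
    if (!is.finite(t_max)) return(list(status = "unbounded", x = NULL))
    t_max <- max(t_max, 0)
    if (leave == 0L) {
      # bound flip: x_q traverses to its opposite bound
      at_upper[q] <- !at_upper[q]
      xval[q] <- if (at_upper[q]) u[q] else l[q]
    } else {
      p <- basis[leave]
      # leaving variable rests at the bound it hit
      hit_lower <- d[leave] > 0
      at_upper[p] <- !hit_lower
      xval[p] <- if (hit_lower) l[p] else u[p]
      in_basis[p] <- FALSE
      in_basis[q] <- TRUE
      xval[q] <- xval[q] + dirsgn * t_max
      basis[leave] <- q
      at_upper[q] <- FALSE
    }
  }
  list(status = "maxiter", x = NULL)
}

.solve_lp <- function(obj, lb, ub, Aeq = NULL, beq = NULL,
                      Aineq = NULL, bineq = NULL, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  A <- NULL
  b <- numeric()
  if (!is.null(Aeq)) {
    A <- Aeq
    b <- beq
  }
  n_slack <- 0L
  if (!is.null(Aineq)) {
    n_slack <- nrow(Aineq)
    if (is.null(A)) {
      A <- Aineq
      b <- bineq
    } else {
      A <- rbind(cbind(A, matrix(0, nrow(A), 0)), Aineq)
      b <- c(b, bineq)
    }
  }
  if (is.null(A)) {  # box-constrained: solve directly
    x <- ifelse((obj > 0) == maximize, ub, lb)
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }
  ncons <- nrow(A)
  neq <- ncons - n_slack
  Afull <- cbind(A, rbind(matrix(0, neq, n_slack), diag(n_slack)))
  cc <- c(obj, rep(0, n_slack))
  l <- c(lb, rep(0, n_slack))
  u <- c(ub, rep(Inf, n_slack))
  res <- .bounded_simplex(cc, Afull, b, l, u, maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = if (res$status == "infeasible") "infeasible"
                  else res$status,
                objective = NA_real_, x = rep(NA_real_, n)))
  }
  x <- res$x[seq_len(n)]
  list(status = "optimal", objective = sum(obj * x), x = x)
}
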