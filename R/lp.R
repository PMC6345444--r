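# Internal optimization wrappers.
#
# Linear programs go through a minimal C binding to the GLPK primal simplex
# (src/glpk_lp.c): optimize obj'x subject to rlb <= Ax <= rub and
# clb <= x <= cub. Quadratic projections (MOMA) use the Goldfarb-Idnani
# active-set solver from the quadprog package.

# status: 1 optimal, -1 infeasible, 2 unbounded, 0 other solver condition
glpk_lp <- function(obj, A, rlb, rub, clb, cub, maximize = TRUE) {
  if (is.null(A)) A <- matrix(0, 0, length(obj))
  storage.mode(A) <- "double"
  res <- .Call(C_glpk_solve, as.double(obj), A, as.double(rlb),
               as.double(rub), as.double(clb), as.double(cub),
               as.logical(maximize))
  status <- switch(as.character(res$status),
                   "5" = 1L,          # GLP_OPT
                   "4" = -1L,         # GLP_NOFEAS
                   "3" = -1L,         # GLP_INFEAS after simplex: no feasible
                   "6" = 2L,          # GLP_UNBND
                   0L)
  list(status = status, x = res$x, objective = res$objective)
}

# legacy-shaped interface used by the flux programs:
# opt obj'x  s.t.  A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0
simplex_call <- function(obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                         A3 = NULL, b3 = NULL, maximize = TRUE) {
  n <- length(obj)
  A <- rbind(A1, A2, A3)
  rlb <- c(rep(-Inf, NROW(A1)), b2, b3)
  rub <- c(b1, rep(Inf, NROW(A2)), b3)
  glpk_lp(obj, A, rlb, rub, clb = rep(0, n), cub = rep(Inf, n),
          maximize = maximize)
}

# opt c'v  s.t.  Aeq v = beq, lb <= v <= ub  (split network: lb >= 0)
lp_solve <- function(obj, Aeq, beq, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(Aeq) == n, length(lb) == n, length(ub) == n)
  if (any(lb < -.tol_zero)) {
    abort("lp_solve expects non-negative lower bounds (split network)")
  }
  res <- glpk_lp(obj, Aeq, rlb = beq, rub = beq, clb = lb, cub = ub,
                 maximize = maximize)
  res$x <- stats::setNames(res$x, colnames(Aeq))
  res
}

# min 1/2 ||x - target||^2  s.t.  Aeq x = beq, lb <= x <= ub.
qp_project <- function(target, Aeq, beq, lb, ub) {
  n <- length(target)
  lo <- which(is.finite(lb)); up <- which(is.finite(ub))
  Amat <- cbind(t(Aeq), diag(n)[, lo, drop = FALSE], -diag(n)[, up, drop = FALSE])
  bvec <- c(beq, lb[lo], -ub[up])
  res <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = target, Amat = Amat,
                       bvec = bvec, meq = nrow(Aeq)),
    error = function(e) NULL
  )
  if (is.null(res)) return(list(status = -1, x = NULL))
  list(status = 1, x = stats::setNames(as.numeric(res$solution), names(target)))
}
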