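# Linear programming front end.
#
# All flux-balance problems in this package are small, dense LPs of the form
#   max/min  c'v   s.t.  S v = 0,  lb <= v <= ub,
# handed to the bounded-variable two-phase simplex in simplex.R.

#' Solve a bounded linear program over an equality-constrained polytope
#'
#' Maximises or minimises `obj' v` subject to `Aeq v = beq` and
#' `lb <= v <= ub`.
#'
#' @param obj numeric objective coefficients, length n.
#' @param Aeq equality-constraint matrix (m x n).
#' @param beq equality right-hand side, length m.
#' @param lb,ub finite variable bounds, length n.
#' @param maximize logical; maximise when `TRUE`.
#'
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` (numeric, `NA` unless optimal) and `solution` (numeric
#'   length-n vector, `NA` unless optimal).
#' @keywords internal
solve_lp <- function(obj, Aeq, beq, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  # Degenerate fully-fixed problem: nothing to optimise.
  if (all(ub - lb <= 0)) {
    v <- lb
    resid <- if (nrow(Aeq)) max(abs(Aeq %*% v - beq)) else 0
    if (resid > 1e-6) {
      return(list(status = "infeasible", objective = NA_real_,
                  solution = rep(NA_real_, n)))
    }
    return(list(status = "optimal", objective = sum(obj * v), solution = v))
  }
  bounded_simplex(obj, Aeq, beq, lb, ub, maximize = maximize)
}
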