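# Bounded-variable primal simplex.
#
# All flux-balance problems here are small dense LPs
#   max/min c'v   s.t.  A v = b,  l <= v <= u,
# solved with the textbook two-phase bounded-variable simplex: nonbasic
# variables sit at a finite bound, the ratio test respects both bounds
# (including bound flips), the basis inverse is maintained by elementary row
# operations, and Bland's rule guards against cycling. Phase 1 drives
# artificial variables out; phase 2 optimises the real objective.

bounded_simplex <- function(cvec, A, b, lower, upper, maximize = TRUE,
                            tol = 1e-9, max_iter = NULL) {
  if (!maximize) {
    out <- bounded_simplex(-cvec, A, b, lower, upper, TRUE, tol, max_iter)
    if (out$status == "optimal") out$objective <- -out$objective
    return(out)
  }
  m <- nrow(A); n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 50L * (n + m + 10L)

  # start nonbasic at the bound with the smaller magnitude
  x <- ifelse(abs(lower) <= abs(upper), lower, upper)
  at_upper <- abs(lower) > abs(upper)
  resid <- b - as.numeric(A %*% x)

  # artificial columns: identity with the sign of the residual
  n_all <- n + m
  Afull <- cbind(A, diag(ifelse(resid >= 0, 1, -1), m))
  lo <- c(lower, rep(0, m))
  up <- c(upper, rep(Inf, m))
  xfull <- c(x, abs(resid))
  status_up <- c(at_upper, rep(FALSE, m))   # nonbasic-at-upper flags
  basis <- n + seq_len(m)
  in_basis <- rep(FALSE, n_all)
  in_basis[basis] <- TRUE
  Binv <- diag(1 / ifelse(resid >= 0, 1, -1), m)  # inverse of the artificial basis

  run_phase <- function(cost, xfull, basis, in_basis, Binv, status_up, bound_hi) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      y <- crossprod(Binv, cost[basis])          # y = Binv' c_B
      d <- cost - as.numeric(crossprod(Afull, y))  # reduced costs
      d[basis] <- 0
      cand_lo <- which(!in_basis & !status_up & d > tol & lo < bound_hi)
      cand_up <- which(!in_basis & status_up & d < -tol)
      cand <- sort(c(cand_lo, cand_up))          # Bland: smallest index
      if (!length(cand)) {
        return(list(status = "optimal", xfull = xfull, basis = basis,
                    in_basis = in_basis, Binv = Binv, status_up = status_up))
      }
      j <- cand[1]
      increase <- !status_up[j]
      w <- as.numeric(Binv %*% Afull[, j])       # basic response to x_j
      # entering variable may move by at most its own range
      t_best <- up[j] - lo[j]
      leave <- -1L                               # -1 = bound flip
      for (k in seq_len(m)) {
        wk <- if (increase) w[k] else -w[k]      # x_Bk changes by -wk * t
        if (wk > tol) {
          tk <- (xfull[basis[k]] - lo[basis[k]]) / wk
        } else if (wk < -tol) {
          tk <- (up[basis[k]] - xfull[basis[k]]) / (-wk)
        } else next
        if (tk < t_best - tol ||
            (tk < t_best + tol && leave > 0 && basis[k] < basis[leave])) {
          t_best <- tk
          leave <- k
        }
      }
      if (!is.finite(t_best)) return(list(status = "unbounded"))
      t_best <- max(t_best, 0)
      step <- if (increase) t_best else -t_best
      xfull[basis] <- xfull[basis] - w * step
      xfull[j] <- xfull[j] + step
      if (leave == -1L) {
        status_up[j] <- !status_up[j]            # bound flip, basis unchanged
      } else {
        out_var <- basis[leave]
        # leaving variable lands on the bound it hit
        wl <- if (increase) w[leave] else -w[leave]
        status_up[out_var] <- wl < 0
        xfull[out_var] <- if (status_up[out_var]) up[out_var] else lo[out_var]
        in_basis[out_var] <- FALSE
        basis[leave] <- j
        in_basis[j] <- TRUE
        # eta update of Binv: pivot on w[leave]
        piv <- w[leave]
        Binv[leave, ] <- Binv[leave, ] / piv
        for (k in seq_len(m)) {
          if (k != leave && abs(w[k]) > 0) {
            Binv[k, ] <- Binv[k, ] - w[k] * Binv[leave, ]
          }
        }
      }
    }
  }

  # phase 1: maximise -(sum of artificials)
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(cost1, xfull, basis, in_basis, Binv, status_up, bound_hi = up)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "unbounded") "infeasible" else ph1$status,
                objective = NA_real_, solution = rep(NA_real_, n)))
  }
  if (sum(ph1$xfull[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  # pin artificials to zero for phase 2
  up2 <- up
  up2[n + seq_len(m)] <- 0
  cost2 <- c(cvec, rep(0, m))
  environment(run_phase)$up <- up2
  ph2 <- run_phase(cost2, ph1$xfull, ph1$basis, ph1$in_basis, ph1$Binv,
                   ph1$status_up, bound_hi = up2)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  v <- ph2$xfull[seq_len(n)]
  v <- pmin(pmax(v, lower), upper)
  list(status = "optimal", objective = sum(cvec * v), solution = v)
}
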