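# Dense bounded-variable primal simplex with dual extraction.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# on the small dense systems arising from core metabolic networks
# (tens of rows/columns).  Two phases: artificial variables are driven
# out first, then the true objective is optimised.  The basis inverse is
# recomputed from scratch every iteration via LU (solve()); at this
# problem size that is cheaper than maintaining an eta file and avoids
# accumulation of update error.

#' Solve a small dense linear program
#'
#' Internal workhorse for the FBA engine.  All bounds must be finite
#' (metabolic models use large finite caps such as +/-1000 rather than
#' infinities).  The dual vector `y` reported for a maximisation problem
#' satisfies `dZ/db = y` at a non-degenerate optimum; for minimisation the
#' sign is flipped so the same identity holds for the stated problem.
#'
#' @param A constraint matrix (m x n), dense numeric.
#' @param b right-hand side, length m.
#' @param obj objective coefficients, length n.
#' @param lb,ub finite variable bounds, length n.
#' @param sense `"max"` or `"min"`.
#' @param tol feasibility / optimality tolerance.
#' @param max_iter iteration cap across both phases.
#' @return list with `status` ("optimal", "infeasible", "unbounded",
#'   "iteration_limit"), `objective`, primal `x`, dual `y` (row duals),
#'   and `basis` (indices of basic columns, structural numbering).
#' @keywords internal
#' @noRd
lp_solve <- function(A, b, obj, lb, ub, sense = "max",
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), y = rep(NA_real_, m), basis = integer()))
  maximize <- identical(sense, "max")
  cvec <- if (maximize) obj else -obj

  # start: structural variables nonbasic at the bound of smaller magnitude
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  resid <- as.numeric(b - A %*% x)
  sgn <- ifelse(resid >= 0, 1, -1)

  # augmented system: structural columns then one artificial per row
  Afull <- cbind(A, diag(sgn, nrow = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  xf <- c(x, abs(resid))
  ntot <- n + m
  status_var <- integer(ntot)               # 0 basic, -1 at lower, +1 at upper
  status_var[seq_len(n)] <- ifelse(abs(lb) <= abs(ub), -1L, 1L)
  basis <- n + seq_len(m)

  run_phase <- function(cost, xf, status_var, basis, iter_budget) {
    degen_count <- 0L
    bland <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > iter_budget)
        return(list(code = "iteration_limit", xf = xf,
                    status_var = status_var, basis = basis, y = NULL))
      B <- Afull[, basis, drop = FALSE]
      nb <- which(status_var != 0L)
      # refresh basic values from the nonbasic ones (keeps Ax = b exact)
      rhs <- b - Afull[, nb, drop = FALSE] %*% xf[nb]
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB))
        return(list(code = "singular", xf = xf, status_var = status_var,
                    basis = basis, y = NULL))
      xf[basis] <- as.numeric(xB)
      y <- as.numeric(solve(t(B), cost[basis]))
      d <- cost[nb] - as.numeric(crossprod(Afull[, nb, drop = FALSE], y))
      improving <- (status_var[nb] == -1L & d > tol) |
                   (status_var[nb] ==  1L & d < -tol)
      if (!any(improving))
        return(list(code = "optimal", xf = xf, status_var = status_var,
                    basis = basis, y = y))
      cand <- nb[improving]
      j <- if (bland) min(cand) else cand[which.max(abs(d[improving]))]
      dir <- if (status_var[j] == -1L) 1 else -1
      w <- as.numeric(solve(B, Afull[, j]))
      # ratio test: how far can x_j move before a basic variable or its own
      # opposite bound blocks it
      chg <- -dir * w                        # d(x_basic)/d(step)
      lims <- rep(Inf, m)
      hit <- integer(m)                      # bound the blocking basic var hits
      for (k in seq_len(m)) {
        bi <- basis[k]
        if (chg[k] < -1e-11) {
          lims[k] <- (xf[bi] - lbf[bi]) / (-chg[k]); hit[k] <- -1L
        } else if (chg[k] > 1e-11 && is.finite(ubf[bi])) {
          lims[k] <- (ubf[bi] - xf[bi]) / chg[k];    hit[k] <- 1L
        }
      }
      lims[lims < 0] <- 0
      step_flip <- ubf[j] - lbf[j]
      step <- min(step_flip, lims)
      if (!is.finite(step))
        return(list(code = "unbounded", xf = xf, status_var = status_var,
                    basis = basis, y = y))
      if (min(lims) <= step_flip) {
        ties <- which(lims <= step + 1e-12)
        leave <- ties[which.min(basis[ties])]  # smallest index: deterministic
        leave_to <- hit[leave]
      } else {
        leave <- 0L                            # entering var flips bound
        leave_to <- 0L
      }
      if (step < 1e-12) {
        degen_count <- degen_count + 1L
        if (degen_count > 5L * (m + n)) bland <- TRUE
      } else degen_count <- 0L
      xf[j] <- xf[j] + dir * step
      xf[basis] <- xf[basis] + chg * step
      if (leave == 0L) {
        status_var[j] <- -status_var[j]      # bound flip, basis unchanged
      } else {
        out <- basis[leave]
        status_var[out] <- leave_to
        xf[out] <- if (leave_to == -1L) lbf[out] else ubf[out]
        status_var[j] <- 0L
        basis[leave] <- j
      }
    }
  }

  # phase 1: minimise sum of artificials == maximise -sum
  cost1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(cost1, xf, status_var, basis, max_iter)
  if (p1$code %in% c("iteration_limit", "singular"))
    return(list(status = p1$code, objective = NA_real_,
                x = rep(NA_real_, n), y = rep(NA_real_, m), basis = integer()))
  art <- n + seq_len(m)
  art_sum <- sum(p1$xf[art])
  if (p1$code != "optimal" || art_sum > 1e-7)
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), y = rep(NA_real_, m), basis = integer()))
  # pin artificials to zero for phase 2
  ubf[art] <- 0
  xf <- p1$xf; status_var <- p1$status_var; basis <- p1$basis
  xf[art][status_var[art] != 0L] <- 0
  cost2 <- c(cvec, rep(0, m))
  p2 <- run_phase(cost2, xf, status_var, basis, max_iter)
  if (p2$code %in% c("iteration_limit", "singular"))
    return(list(status = p2$code, objective = NA_real_,
                x = rep(NA_real_, n), y = rep(NA_real_, m), basis = integer()))
  if (p2$code == "unbounded")
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n), y = rep(NA_real_, m), basis = integer()))
  xsol <- p2$xf[seq_len(n)]
  zval <- sum(cvec * xsol)
  yvec <- p2$y
  if (!maximize) { zval <- -zval; yvec <- -yvec }
  list(status = "optimal", objective = zval, x = xsol, y = yvec,
       basis = p2$basis[p2$basis <= n])
}
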