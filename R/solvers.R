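# Internal optimisation layer.
#
# All flux computations in the package reduce to linear programs (LP) over
# the flux polytope {v : S v = 0, lb <= v <= ub, A v <= b} or to strictly
# convex quadratic programs (QP) over the same region. The QP primitive is
# quadprog::solve.QP (Goldfarb-Idnani dual active set; numerically solid).
# LPs are solved *through* that primitive: feasibility of
# {P, c'v >= theta} is decided by a strictly convex projection QP, and
# bisection on theta converges to the LP optimum. Because every feasible
# probe returns an attaining point, the reported optimum is always
# achieved by a feasible vector, and the scheme is deterministic. On the
# small, bounded models this package targets (tens of reactions) the
# 40-odd QP probes per LP are cheap, and the approach avoids the
# degeneracy pitfalls of textbook big-M simplex implementations.
# Mixed-integer searches (iMAT, the transformation search) are
# branch-and-bound routines built on these primitives and live next to
# their algorithms.

# tolerance used throughout for feasibility checks on returned fluxes
MD_FEAS_TOL <- 1e-6

# absolute/relative objective tolerance of the LP bisection
MD_LP_TOL <- 1e-8

#' Strictly convex QP: minimise 0.5 * sum w (v - target)^2
#' subject to Aeq v = beq, lb <= v <= ub, Ain v <= bin.
#' @noRd
#' @return list(v, dist2) with dist2 = sum w (v - target)^2, or NULL when
#'   the region is infeasible
qp_project <- function(target, Aeq, beq, lb, ub, Ain = NULL, bin = NULL,
                       weights = NULL) {
  n <- length(target)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(all(w > 0))
  if (any(lb > ub + 1e-12)) return(NULL)
  Aeq <- as.matrix(Aeq)
  if (!is.null(Ain)) Ain <- as.matrix(Ain)
  # eliminate variables pinned by lb == ub: the dual active-set method
  # rejects zero-width boxes expressed as paired inequalities
  fixed <- which(ub - lb < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  vfix <- lb[fixed]
  if (length(free) == 0) {
    resid <- abs(as.vector(Aeq %*% vfix) - beq)
    if (any(resid > 1e-8)) return(NULL)
    if (!is.null(Ain) && any(as.vector(Ain %*% vfix) > bin + 1e-8)) {
      return(NULL)
    }
    return(list(v = vfix, dist2 = sum(w * (vfix - target)^2)))
  }
  beq_f <- beq - if (length(fixed)) as.vector(
    Aeq[, fixed, drop = FALSE] %*% vfix) else 0
  bin_f <- if (!is.null(Ain)) {
    bin - if (length(fixed)) as.vector(Ain[, fixed, drop = FALSE] %*% vfix)
          else 0
  }
  Aeq_f <- Aeq[, free, drop = FALSE]
  Ain_f <- if (!is.null(Ain)) Ain[, free, drop = FALSE]
  # drop all-zero equality rows (arise after fixing); check consistency
  zero_rows <- rowSums(abs(Aeq_f)) < 1e-14
  if (any(zero_rows)) {
    if (any(abs(beq_f[zero_rows]) > 1e-8)) return(NULL)
    Aeq_f <- Aeq_f[!zero_rows, , drop = FALSE]
    beq_f <- beq_f[!zero_rows]
  }
  nf <- length(free)
  Dmat <- diag(w[free], nf)
  dvec <- w[free] * target[free]
  # quadprog convention: A^T v >= b, first meq rows are equalities
  Amat <- t(rbind(Aeq_f,
                  diag(nf),          # v >= lb
                  -diag(nf),         # -v >= -ub
                  if (!is.null(Ain_f)) -Ain_f))
  bvec <- c(beq_f, lb[free], -ub[free], if (!is.null(Ain_f)) -bin_f)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = nrow(Aeq_f)),
    error = function(e) NULL
  )
  if (is.null(sol)) return(NULL)
  v <- numeric(n)
  v[fixed] <- vfix
  v[free] <- pmin(pmax(sol$solution, lb[free]), ub[free])
  list(v = v, dist2 = sum(w * (v - target)^2))
}

# Projection with target fallbacks: the dual active-set method can fail
# from a far-away unconstrained start on degenerate regions, so probe
# from several targets before declaring infeasibility.
#' @noRd
qp_probe <- function(Aeq, beq, lb, ub, Ain = NULL, bin = NULL,
                     target = NULL) {
  targets <- list(target, (lb + ub) / 2, pmin(pmax(0, lb), ub), lb)
  for (tg in targets) {
    if (is.null(tg)) next
    sol <- qp_project(tg, Aeq, beq, lb, ub, Ain, bin)
    if (!is.null(sol)) return(sol)
  }
  NULL
}

# Feasibility probe for {Aeq v = beq, lb<=v<=ub, Ain v <= bin}.
#' @noRd
region_feasible <- function(Aeq, beq, lb, ub, Ain = NULL, bin = NULL) {
  !is.null(qp_probe(Aeq, beq, lb, ub, Ain, bin))
}

#' LP by bisection on the objective level set
#' @noRd
#' @param obj objective coefficients (length n)
#' @param Aeq,beq equality constraints Aeq v = beq
#' @param lb,ub finite elementwise bounds
#' @param Ain,bin optional inequality constraints Ain v <= bin
#' @param sense "max" or "min"
#' @return list(v, val) or NULL when infeasible
lp_solve <- function(obj, Aeq, beq, lb, ub, Ain = NULL, bin = NULL,
                     sense = c("max", "min")) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(is.finite(ub)))
  cc <- if (sense == "max") obj else -obj   # always maximise cc'v
  base <- qp_probe(Aeq, beq, lb, ub, Ain, bin)
  if (is.null(base)) return(NULL)
  v_best <- base$v
  f_lo <- sum(cc * v_best)
  # box relaxation bounds the optimum from above
  f_hi <- sum(pmax(cc, 0) * ub + pmin(cc, 0) * lb)
  while (f_hi - f_lo > MD_LP_TOL * max(1, abs(f_lo))) {
    theta <- (f_lo + f_hi) / 2
    probe <- qp_probe(Aeq, beq, lb, ub,
                      Ain = rbind(Ain, -cc), bin = c(bin, -theta))
    if (is.null(probe)) {
      f_hi <- theta
    } else {
      v_best <- probe$v
      f_lo <- max(theta, sum(cc * v_best))
    }
  }
  val <- sum(obj * v_best)
  list(v = v_best, val = val)
}
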