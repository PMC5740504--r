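# Context-specific flux states.
#
# Two classic expression-integration methods constrain the flux space with
# one transcriptomic profile:
#   * GIMME: an LP that guarantees a fraction of the objective optimum and
#     minimises (threshold - expression)-weighted flux through reactions
#     whose expression falls below a threshold;
#   * iMAT: a mixed-integer search for a flux state maximising agreement
#     with discrete high/low reaction activity calls (a "high" reaction
#     should carry at least `activation_eps` flux in either direction, a
#     "low" reaction should carry none).
# A seeded hit-and-run sampler explores the (optionally further
# constrained) flux polytope.

as_expr_vector <- function(expr) {
  if (is.data.frame(expr)) {
    stopifnot(all(c("gene", "value") %in% names(expr)))
    if (anyDuplicated(expr$gene)) stop("duplicated gene ids in profile",
                                       call. = FALSE)
    v <- expr$value
    names(v) <- expr$gene
    expr <- v
  }
  stopifnot(is.numeric(expr), !is.null(names(expr)))
  if (any(!is.finite(expr))) stop("expression values must be finite",
                                  call. = FALSE)
  expr
}

#' Map a gene expression profile onto reactions via GPR algebra
#'
#' min over AND branches, max over OR branches; reactions without a rule
#' (or without any measured gene) get `NA`.
#'
#' @param model a `metabolic_model`.
#' @param expr named numeric vector or tibble with columns `gene`, `value`.
#' @return tibble with columns `reaction`, `expression`.
#' @export
reaction_expression <- function(model, expr) {
  e <- as_expr_vector(expr)
  tibble::tibble(
    reaction = model$reactions$id,
    expression = vapply(model$reactions$id, function(r)
      gpr_eval_expr(model$gpr[[r]], e), numeric(1))
  )
}

#' Discretise reaction activity for iMAT
#'
#' Genes are called high/low against `mean +/- k * sd` of the profile (a
#' convention from the iMAT literature), mapped through GPR algebra.
#'
#' @param model a `metabolic_model`.
#' @param expr expression profile (named vector or `gene`/`value` tibble).
#' @param k width of the moderate band in standard deviations.
#' @return tibble with columns `reaction`, `expression`, `call`
#'   (`"high"`, `"low"` or `"moderate"`).
#' @export
reaction_activity_calls <- function(model, expr, k = 0.5) {
  e <- as_expr_vector(expr)
  hi <- mean(e) + k * stats::sd(e)
  lo <- mean(e) - k * stats::sd(e)
  rx <- reaction_expression(model, e)
  dplyr::mutate(rx, call = dplyr::case_when(
    is.na(.data$expression) ~ "moderate",
    .data$expression >= hi ~ "high",
    .data$expression <= lo ~ "low",
    TRUE ~ "moderate"
  ))
}

#' GIMME: expression-penalised flux consistent with an objective
#'
#' Solves the LP minimising `sum_r w_r |v_r|` over reactions whose
#' GPR-mapped expression is below `threshold` (weight
#' `w_r = threshold - e_r`), subject to steady state, bounds, and the
#' objective keeping at least `objective_fraction` of its FBA optimum.
#' Absolute values are linearised by flux splitting `v = v+ - v-`.
#'
#' @param model a `metabolic_model`.
#' @param expr expression profile.
#' @param threshold absolute expression threshold; when `NULL`, the
#'   `threshold_quantile` of the profile is used.
#' @param threshold_quantile quantile defining the default threshold.
#' @param objective_fraction required fraction of the objective optimum.
#' @return `flux_distribution` (provenance `"gimme"`) with attributes
#'   `penalty` (the achieved inconsistency score) and `threshold`.
#' @export
gimme <- function(model, expr, threshold = NULL, threshold_quantile = 0.25,
                  objective_fraction = 0.9) {
  e <- as_expr_vector(expr)
  if (is.null(threshold)) {
    threshold <- unname(stats::quantile(e, threshold_quantile))
  }
  opt <- fba(model)$objective_value
  if (opt <= MD_FEAS_TOL && objective_fraction > 0) {
    stop("objective optimum is ", format(opt),
         "; no objective functionality to protect at fraction ",
         objective_fraction, call. = FALSE)
  }
  rx <- reaction_expression(model, e)
  w <- pmax(threshold - rx$expression, 0)
  w[is.na(w)] <- 0
  n <- nrow(model$reactions)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  # split v = vp - vm, vp, vm >= 0
  obj2 <- c(w, w)
  Aeq2 <- cbind(as.matrix(model$S), -as.matrix(model$S))
  lb2 <- rep(0, 2 * n)
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  cvec <- numeric(n); cvec[rxn_index(model, model$objective_id)] <- 1
  Ain2 <- matrix(c(-cvec, cvec), nrow = 1)
  bin2 <- -objective_fraction * opt
  # enforce one-sided bounds that the split ranges alone do not carry
  need_lo <- which(lb > 0); need_hi <- which(ub < 0)
  for (i in need_lo) {
    row <- numeric(2 * n); row[i] <- -1; row[n + i] <- 1
    Ain2 <- rbind(Ain2, row); bin2 <- c(bin2, -lb[i])
  }
  for (i in need_hi) {
    row <- numeric(2 * n); row[i] <- 1; row[n + i] <- -1
    Ain2 <- rbind(Ain2, row); bin2 <- c(bin2, ub[i])
  }
  lp <- lp_solve(obj2, Aeq2, rep(0, nrow(model$metabolites)), lb2, ub2,
                 Ain2, bin2, sense = "min")
  if (is.null(lp)) {
    stop("GIMME LP infeasible at objective fraction ", objective_fraction,
         call. = FALSE)
  }
  v <- lp$v[seq_len(n)] - lp$v[n + seq_len(n)]
  v <- pmin(pmax(v, lb), ub)
  fd <- flux_distribution(model, v, provenance = "gimme")
  attr(fd, "penalty") <- lp$val
  attr(fd, "threshold") <- threshold
  fd
}

#' iMAT: flux state maximising agreement with activity calls
#'
#' Branch-and-bound over the per-reaction activity indicators: a "high"
#' call is satisfied when `|v| >= activation_eps` (either direction), a
#' "low" call when `v = 0`. Nodes are pruned by LP feasibility of the
#' partial assignment and by the remaining attainable agreement. The flux
#' returned is the minimal-norm point of the best region found.
#'
#' @param model a `metabolic_model`.
#' @param calls tibble from [reaction_activity_calls()] (columns
#'   `reaction`, `call`).
#' @param activation_eps minimum flux magnitude counting as "active".
#' @return `flux_distribution` (provenance `"imat"`) with attribute
#'   `agreement` — the number of satisfied calls.
#' @export
imat <- function(model, calls, activation_eps = 1) {
  stopifnot(all(c("reaction", "call") %in% names(calls)))
  called <- calls[calls$call %in% c("high", "low"), ]
  lb0 <- model$reactions$lb; ub0 <- model$reactions$ub
  p <- model_lp_parts(model)
  if (!region_feasible(p$Aeq, p$beq, lb0, ub0)) {
    stop("model is infeasible", call. = FALSE)
  }
  idx <- rxn_index(model, called$reaction)
  kind <- called$call
  best <- new.env(parent = emptyenv())
  best$score <- -1L
  best$lb <- lb0; best$ub <- ub0
  recurse <- function(i, lb, ub, score) {
    if (score + (length(idx) - i + 1L) <= best$score) return()
    if (i > length(idx)) {
      if (score > best$score) {
        best$score <- score; best$lb <- lb; best$ub <- ub
      }
      return()
    }
    r <- idx[i]
    branches <- list()
    if (kind[i] == "high") {
      if (ub[r] >= activation_eps) {
        b <- list(lb = lb, ub = ub, gain = 1L)
        b$lb[r] <- max(lb[r], activation_eps)
        branches <- c(branches, list(b))
      }
      if (lb[r] <= -activation_eps) {
        b <- list(lb = lb, ub = ub, gain = 1L)
        b$ub[r] <- min(ub[r], -activation_eps)
        branches <- c(branches, list(b))
      }
    } else {  # low: satisfied means no flux
      if (lb[r] <= 0 && ub[r] >= 0) {
        b <- list(lb = lb, ub = ub, gain = 1L)
        b$lb[r] <- 0; b$ub[r] <- 0
        branches <- c(branches, list(b))
      }
    }
    branches <- c(branches, list(list(lb = lb, ub = ub, gain = 0L)))
    for (b in branches) {
      if (b$gain > 0L &&
          !region_feasible(p$Aeq, p$beq, b$lb, b$ub)) next
      recurse(i + 1L, b$lb, b$ub, score + b$gain)
    }
  }
  recurse(1L, lb0, ub0, 0L)
  qp <- qp_project(rep(0, length(lb0)), p$Aeq, p$beq, best$lb, best$ub)
  fd <- flux_distribution(model, qp$v, provenance = "imat")
  attr(fd, "agreement") <- best$score
  attr(fd, "activation_eps") <- activation_eps
  fd
}

#' Hit-and-run sampling of the flux polytope
#'
#' Uniform-direction hit-and-run in the null space of S (restricted to the
#' non-fixed coordinates), started from the projection of the bound-box
#' midpoint onto the polytope. Seeded and fully reproducible.
#'
#' @param model a `metabolic_model`.
#' @param fixed_constraints optional tibble `id`, `lb`, `ub` of bound
#'   overrides defining the sampled region.
#' @param n number of samples.
#' @param seed integer seed.
#' @param burnin,thin chain warm-up and thinning (kept fixed by default).
#' @return list of `n` `flux_distribution`s (provenance `"sample"`).
#' @export
sample_flux_space <- function(model, fixed_constraints = NULL, n = 100,
                              seed = 1, burnin = 100, thin = 5) {
  if (!is.null(fixed_constraints)) {
    model <- set_bounds(model, fixed_constraints)
  }
  lb <- model$reactions$lb; ub <- model$reactions$ub
  p <- model_lp_parts(model)
  if (!region_feasible(p$Aeq, p$beq, lb, ub)) {
    stop("sampling region is infeasible", call. = FALSE)
  }
  nr <- length(lb)
  # effective per-reaction flux ranges: the walk is preconditioned by
  # them (not by the raw bounds) so that dimensions whose reachable range
  # is much narrower than their box do not throttle the step size
  ranges <- vapply(seq_len(nr), function(i) {
    obj <- numeric(nr); obj[i] <- 1
    lo <- lp_solve(obj, p$Aeq, p$beq, lb, ub, sense = "min")
    hi <- lp_solve(obj, p$Aeq, p$beq, lb, ub, sense = "max")
    c(lo$val, hi$val)
  }, numeric(2))
  start <- qp_probe(p$Aeq, p$beq, lb, ub,
                    target = colMeans(ranges))
  fixed <- which(ranges[2, ] - ranges[1, ] < 1e-9)
  width <- pmax(ranges[2, ] - ranges[1, ], 1e-9)
  width[fixed] <- 1
  Saug <- p$Aeq %*% diag(width, nr)
  if (length(fixed)) {
    E <- matrix(0, length(fixed), nr)
    E[cbind(seq_along(fixed), fixed)] <- 1
    Saug <- rbind(Saug, E)
  }
  sv <- svd(Saug, nu = 0, nv = nr)
  rank <- sum(sv$d > max(dim(Saug)) * max(sv$d, 0) * 1e-12)
  N <- if (rank < nr) sv$v[, (rank + 1):nr, drop = FALSE]
       else matrix(0, nr, 0)
  k <- ncol(N)
  x0 <- start$v
  draws <- withr::with_seed(seed, {
    out <- vector("list", n)
    x <- x0
    got <- 0L; iter <- 0L
    if (k == 0L) {
      for (j in seq_len(n)) out[[j]] <- x
    } else {
      while (got < n) {
        iter <- iter + 1L
        d <- width * as.vector(N %*% stats::rnorm(k))
        nd <- sqrt(sum(d^2))
        if (nd < 1e-12) next
        d <- d / nd
        tmin <- -Inf; tmax <- Inf
        for (i in seq_len(nr)) {
          if (abs(d[i]) < 1e-11) next
          a <- (lb[i] - x[i]) / d[i]
          b <- (ub[i] - x[i]) / d[i]
          tmin <- max(tmin, min(a, b))
          tmax <- min(tmax, max(a, b))
        }
        if (!is.finite(tmin) || !is.finite(tmax) || tmax < tmin) next
        x <- x + stats::runif(1, tmin, tmax) * d
        # keep the chain exactly on the steady-state affine slice
        # (projection in the width-scaled metric)
        y <- (x - x0) / width
        x <- x0 + width * as.vector(N %*% crossprod(N, y))
        x <- pmin(pmax(x, lb), ub)
        if (iter > burnin && iter %% thin == 0L) {
          got <- got + 1L
          out[[got]] <- x
        }
      }
    }
    out
  })
  lapply(draws, function(v)
    validate_flux(model, flux_distribution(model, v, provenance = "sample")))
}
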