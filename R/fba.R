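# Flux balance analysis and flux variability analysis.
#
# FBA solves max/min c'v subject to the steady-state constraint S v = 0 and
# the flux capacity bounds v_min <= v <= v_max. Because LP optima are
# usually degenerate, the returned flux vector is made reproducible by a
# secondary stage that picks, among all optimal solutions, the unique one
# of minimal Euclidean norm (a strictly convex projection, so the
# representative is well defined and solver-order independent).

#' Construct a flux distribution
#' @param model a `metabolic_model`.
#' @param v numeric flux vector aligned to the model's reactions.
#' @param provenance label: one of fba, gimme, imat, moma, sample.
#' @param objective_value flux through the objective reaction (computed
#'   from `v` when omitted).
#' @return object of class `flux_distribution`.
#' @export
flux_distribution <- function(model, v, provenance = "fba",
                              objective_value = NULL) {
  stopifnot(length(v) == nrow(model$reactions))
  names(v) <- model$reactions$id
  if (is.null(objective_value)) {
    objective_value <- unname(v[model$objective_id])
  }
  structure(list(v = v, objective_value = objective_value,
                 provenance = provenance),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution:", x$provenance, "> ", length(x$v),
      " reactions, objective = ", format(x$objective_value, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Shared feasibility validator for flux distributions
#'
#' Asserts the steady-state residual `max |S v|` and the bound violations
#' are within `tol`. Every flux vector the package returns passes through
#' this check.
#'
#' @param model a `metabolic_model`.
#' @param flux a `flux_distribution` or bare numeric vector.
#' @param tol feasibility tolerance (flux units).
#' @return the flux, invisibly; errors on violation.
#' @export
validate_flux <- function(model, flux, tol = 1e-6) {
  v <- if (inherits(flux, "flux_distribution")) flux$v else flux
  stopifnot(length(v) == nrow(model$reactions))
  resid <- max(abs(as.vector(model$S %*% v)))
  if (resid > tol) {
    stop("flux violates steady state: max |S v| = ", format(resid),
         call. = FALSE)
  }
  lo <- min(v - model$reactions$lb)
  hi <- min(model$reactions$ub - v)
  if (lo < -tol || hi < -tol) {
    stop("flux violates bounds by ", format(max(-lo, -hi)), call. = FALSE)
  }
  invisible(flux)
}

model_lp_parts <- function(model) {
  list(Aeq = as.matrix(model$S),
       beq = rep(0, nrow(model$metabolites)),
       lb = model$reactions$lb,
       ub = model$reactions$ub)
}

#' Flux balance analysis
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to optimise (default: the model objective).
#' @param direction `"max"` or `"min"`.
#' @return a `flux_distribution` with provenance `"fba"`; its
#'   `objective_value` is the LP optimum and its flux vector is the
#'   minimal-norm optimal solution.
#' @export
fba <- function(model, objective_id = model$objective_id,
                direction = c("max", "min")) {
  direction <- match.arg(direction)
  p <- model_lp_parts(model)
  obj <- numeric(nrow(model$reactions))
  obj[rxn_index(model, objective_id)] <- 1
  lp <- lp_solve(obj, p$Aeq, p$beq, p$lb, p$ub, sense = direction)
  if (is.null(lp)) {
    if (region_feasible(p$Aeq, p$beq, p$lb, p$ub)) {
      stop("LP solver failed on a feasible model", call. = FALSE)
    }
    stop("model is infeasible (no steady-state flux satisfies the bounds)",
         call. = FALSE)
  }
  # secondary stage: unique minimal-norm optimum
  sgn <- if (direction == "max") 1 else -1
  qp <- qp_project(rep(0, length(obj)), p$Aeq, p$beq, p$lb, p$ub,
                   Ain = matrix(-sgn * obj, nrow = 1),
                   bin = -sgn * lp$val + 1e-9)
  v <- if (is.null(qp)) lp$v else qp$v
  flux_distribution(model, v, provenance = "fba",
                    objective_value = lp$val)
}

#' Flux variability analysis
#'
#' Per-reaction flux minima and maxima subject to the objective retaining
#' at least `objective_fraction` of its FBA optimum.
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to scan (default: all).
#' @param objective_fraction fraction in `[0, 1]` of the FBA optimum that
#'   must be maintained.
#' @return tibble with columns `id`, `min`, `max`.
#' @export
fva <- function(model, reactions = model$reactions$id,
                objective_fraction = 0) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  p <- model_lp_parts(model)
  n <- nrow(model$reactions)
  opt <- fba(model)$objective_value
  cvec <- numeric(n); cvec[rxn_index(model, model$objective_id)] <- 1
  Ain <- matrix(-cvec, nrow = 1)
  bin <- -objective_fraction * opt
  out <- purrr::map_dfr(reactions, function(id) {
    obj <- numeric(n); obj[rxn_index(model, id)] <- 1
    lo <- lp_solve(obj, p$Aeq, p$beq, p$lb, p$ub, Ain, bin, sense = "min")
    hi <- lp_solve(obj, p$Aeq, p$beq, p$lb, p$ub, Ain, bin, sense = "max")
    if (is.null(lo) || is.null(hi)) {
      stop("FVA infeasible at objective fraction ", objective_fraction,
           call. = FALSE)
    }
    tibble::tibble(id = id, min = lo$val, max = hi$val)
  })
  dplyr::mutate(out, min = pmin(.data$min, .data$max))
}
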