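# broom-style tidiers for fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn km_delta_auc tidy(): per-bin survival curve steps as a
#'   tibble (`bin`, `time`, `n_risk`, `n_event`, `surv`).
#' @param x a `km_result`.
#' @param ... unused.
#' @method tidy km_result
#' @export
tidy.km_result <- function(x, ...) {
  one <- function(fit, bin) tibble::tibble(
    bin = bin, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, surv = fit$surv
  )
  dplyr::bind_rows(one(x$fit_low, "low"), one(x$fit_high, "high"))
}

#' @describeIn km_delta_auc glance(): one-row summary with `delta_auc`,
#'   per-bin areas, horizon and bin sizes.
#' @method glance km_result
#' @export
glance.km_result <- function(x, ...) {
  tibble::tibble(gene = x$gene, split = x$split, delta_auc = x$delta_auc,
                 auc_low = x$auc_low, auc_high = x$auc_high,
                 horizon = x$horizon, n_low = x$n_low, n_high = x$n_high)
}

#' @describeIn solve_mta tidy(): one row per R_F/R_B reaction with its
#'   achieved status.
#' @param x an `mta_result`.
#' @param ... unused.
#' @method tidy mta_result
#' @export
tidy.mta_result <- function(x, ...) {
  tibble::tibble(
    reaction = c(x$success, x$unsuccess),
    achieved = rep(c(TRUE, FALSE),
                   c(length(x$success), length(x$unsuccess)))
  )
}

#' @describeIn solve_mta glance(): one-row summary (candidate, ts,
#'   success counts, status).
#' @method glance mta_result
#' @export
glance.mta_result <- function(x, ...) {
  tibble::tibble(candidate = x$candidate, ts = x$ts,
                 n_success = length(x$success),
                 n_required = length(x$success) + length(x$unsuccess),
                 objective = x$objective, status = x$status)
}

#' @describeIn rank_candidates tidy(): the ranking as a plain tibble.
#' @param x an `mta_ranking`.
#' @param ... unused.
#' @method tidy mta_ranking
#' @export
tidy.mta_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) %in% c(
    "candidate", "ts", "n_success", "status", "is_control", "percentile")])
}

#' @describeIn rank_candidates glance(): one-row summary (candidate
#'   count, control TS, top candidate).
#' @method glance mta_ranking
#' @export
glance.mta_ranking <- function(x, ...) {
  genes <- x[!x$is_control, ]
  tibble::tibble(n_candidates = nrow(genes),
                 control_ts = attr(x, "control_ts"),
                 top_candidate = genes$candidate[1],
                 top_ts = genes$ts[1])
}

#' @describeIn compare_kd_oe tidy(): the per-read-out rank-sum tests.
#' @param x a `phenotype_comparison`.
#' @param ... unused.
#' @method tidy phenotype_comparison
#' @export
tidy.phenotype_comparison <- function(x, ...) x$tests

#' @describeIn compare_kd_oe glance(): per-read-out arm medians, wide.
#' @method glance phenotype_comparison
#' @export
glance.phenotype_comparison <- function(x, ...) {
  meds <- dplyr::summarise(
    dplyr::group_by(x$samples, .data$arm),
    dplyr::across(dplyr::all_of(names(x$readouts)), stats::median),
    .groups = "drop")
  tidyr::pivot_wider(tidyr::pivot_longer(meds, -"arm",
                                         names_to = "readout"),
                     names_from = c("readout", "arm"),
                     values_from = "value")
}

#' @describeIn stage_specific_moma tidy(): per-sample distances.
#' @param x a `stage_profile`.
#' @param ... unused.
#' @method tidy stage_profile
#' @export
tidy.stage_profile <- function(x, ...) x$distances

#' @describeIn stage_specific_moma glance(): per-stage median distances,
#'   wide.
#' @method glance stage_profile
#' @export
glance.stage_profile <- function(x, ...) {
  meds <- dplyr::summarise(dplyr::group_by(x$distances, .data$stage),
                           median_distance = stats::median(.data$distance),
                           .groups = "drop")
  tidyr::pivot_wider(meds, names_from = "stage",
                     values_from = "median_distance",
                     names_prefix = "stage")
}
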