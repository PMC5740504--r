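# Oncogenic transformation scores (OTS).
#
# One MTA ranking per matched sample pair yields, for each candidate, a
# binary indicator I_ij (did candidate i beat the no-perturbation control
# in pair j?). These are aggregated across pairs as
#     OTS(i) = sum_j I_ij * (1 - P_j),
# where P_j is the fraction of candidates in pair j that beat the control
# — pairs in which few candidates score are weighted more heavily. A gene
# keyed by several reactions inherits the maximum of their scores, and
# per-dataset gene tables are summed across datasets.
#
# Note on P: the source description is ambiguous between a count and a
# probability; only the fraction reading keeps 1 - P inside [0, 1], so
# the fraction is what is implemented.

#' Per-pair outcome of an MTA ranking
#'
#' @param ranking an `mta_ranking` from [rank_candidates()] (must contain
#'   the control row).
#' @param pair_id optional label for the pair.
#' @return tibble of class `pair_outcome` with columns `id`, `ts`,
#'   `beat_control` (strict inequality; ties count as failure) and
#'   attribute `p_beat` — the fraction of candidates beating the control.
#' @export
pair_outcome <- function(ranking, pair_id = NULL) {
  stopifnot(all(c("candidate", "ts", "is_control") %in% names(ranking)))
  if (!any(ranking$is_control)) {
    stop("ranking has no control entry", call. = FALSE)
  }
  control_ts <- ranking$ts[ranking$is_control][1]
  cand <- ranking[!ranking$is_control, ]
  out <- tibble::tibble(
    id = cand$candidate,
    ts = cand$ts,
    beat_control = cand$ts > control_ts
  )
  out <- structure(out, class = c("pair_outcome", class(out)))
  attr(out, "p_beat") <- mean(out$beat_control)
  attr(out, "pair_id") <- pair_id
  out
}

#' Aggregate pair outcomes into OTS
#'
#' `OTS(i) = sum_j I_ij * (1 - P_j)`; candidates absent from a pair
#' contribute 0 for that pair.
#'
#' @param outcomes list of [pair_outcome()] tibbles.
#' @param dataset label attached to the result.
#' @return tibble of class `ots_table` with columns `id`, `ots`, sorted by
#'   `ots` descending.
#' @export
aggregate_ots <- function(outcomes, dataset = "dataset") {
  stopifnot(length(outcomes) >= 1)
  per_pair <- purrr::imap_dfr(outcomes, function(o, j) {
    if (!inherits(o, "pair_outcome")) {
      stop("outcomes must be pair_outcome objects", call. = FALSE)
    }
    tibble::tibble(id = o$id,
                   w = as.numeric(o$beat_control) * (1 - attr(o, "p_beat")))
  })
  tab <- dplyr::summarise(dplyr::group_by(per_pair, .data$id),
                          ots = sum(.data$w), .groups = "drop")
  tab <- dplyr::arrange(tab, dplyr::desc(.data$ots), .data$id)
  structure(tab, class = c("ots_table", class(tab)), dataset = dataset,
            n_pairs = length(outcomes))
}

#' Map reaction-level OTS to genes
#'
#' Each gene receives the maximum OTS over the reactions whose GPR
#' mentions it; genes absent from every GPR do not appear.
#'
#' @param reaction_ots an `ots_table` keyed by reaction ids.
#' @param model a `metabolic_model`.
#' @return gene-level `ots_table`.
#' @export
gene_ots <- function(reaction_ots, model) {
  gmap <- gene_reaction_map(model)
  joined <- dplyr::inner_join(gmap, reaction_ots,
                              by = c(reaction = "id"))
  tab <- dplyr::summarise(dplyr::group_by(joined, .data$gene),
                          ots = max(.data$ots), .groups = "drop")
  tab <- dplyr::arrange(dplyr::rename(tab, id = "gene"),
                        dplyr::desc(.data$ots), .data$id)
  structure(tab, class = c("ots_table", class(tab)),
            dataset = attr(reaction_ots, "dataset"))
}

#' Sum gene-level OTS across datasets
#'
#' @param tables list of gene-level `ots_table`s; ids missing from a
#'   dataset contribute 0.
#' @return `ots_table` with per-dataset columns `ots_<label>` and the
#'   total `ots_sum`, sorted by `ots_sum` descending.
#' @export
sum_across_datasets <- function(tables) {
  stopifnot(length(tables) >= 1)
  labels <- purrr::imap_chr(tables, function(t, i)
    attr(t, "dataset") %||% paste0("dataset", i))
  wide <- purrr::reduce(purrr::map2(tables, labels, function(t, lab) {
    tibble::tibble(id = t$id, !!paste0("ots_", lab) := t$ots)
  }), dplyr::full_join, by = "id")
  wide[is.na(wide)] <- 0
  wide$ots_sum <- rowSums(wide[, -1, drop = FALSE])
  wide <- dplyr::arrange(wide, dplyr::desc(.data$ots_sum), .data$id)
  structure(wide, class = c("ots_table", class(wide)), dataset = "sum")
}
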