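# End-to-end two-step discovery.
#
# Step 1 (genomic funnel): differential expression -> copy-number loss ->
# survival dAUC < 0, intersected with the model's gene set.
# Step 2 (metabolic modeling): per matched pair, an MTA ranking of all
# model genes against the no-perturbation control; per-pair outcomes are
# aggregated into oncogenic transformation scores per dataset and summed
# across datasets. The report lists the funnel survivors with their OTS
# and screen statistics, sorted by summed OTS.

#' Assemble a discovery-pipeline configuration
#'
#' @param model a `metabolic_model`.
#' @param cohort a [cohort_table()] with CN and survival blocks.
#' @param mta_datasets named list of datasets; each dataset is a list of
#'   matched pairs, each pair a list with elements `source` and `target`
#'   (expression profiles).
#' @param alpha differential-expression level (default 0.001).
#' @param q_threshold copy-number Q-value threshold (default 0.25).
#' @param km_split survival split mode, `"median"` or `"quartiles"`.
#' @param params an [mta_params()] object.
#' @param reference_engine source-state inference for MTA: `"imat"`
#'   (activity-call MILP) or `"fba"` (plain optimal state).
#' @param seed integer seed recorded in the run log (all pipeline stages
#'   are deterministic).
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(model, cohort, mta_datasets, alpha = 0.001,
                             q_threshold = 0.25, km_split = "median",
                             params = mta_params(),
                             reference_engine = c("imat", "fba"),
                             seed = 1) {
  reference_engine <- match.arg(reference_engine)
  stopifnot(inherits(model, "metabolic_model"),
            inherits(cohort, "cohort_table"),
            is.list(mta_datasets), length(mta_datasets) >= 1)
  if (is.null(names(mta_datasets))) {
    names(mta_datasets) <- paste0("dataset", seq_along(mta_datasets))
  }
  structure(list(model = model, cohort = cohort,
                 mta_datasets = mta_datasets, alpha = alpha,
                 q_threshold = q_threshold, km_split = km_split,
                 params = params, reference_engine = reference_engine,
                 seed = seed),
            class = "discovery_config")
}

mta_reference_state <- function(model, source, engine) {
  if (engine == "imat") {
    imat(model, reaction_activity_calls(model, source))
  } else {
    fba(model)
  }
}

#' Run the two-step discovery pipeline
#'
#' @param config a [discovery_config()].
#' @return tibble of class `candidate_table`: one row per funnel-surviving
#'   model gene with per-dataset OTS, `ots_sum`, `de_p`, `cn_q` and
#'   `km_delta_auc`, sorted by `ots_sum` descending. The run log
#'   (thresholds, per-stage gene counts) and the full OTS table over all
#'   model genes are attached as attributes `log` and `full_ots`.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "discovery_config"))
  model <- config$model
  cohort <- config$cohort
  de <- tryCatch(diff_expr_screen(cohort, config$alpha),
                 error = function(e) stop("screen stage (DE): ",
                                          conditionMessage(e),
                                          call. = FALSE))
  cn <- tryCatch(cn_screen(cohort, config$q_threshold, genes = de$gene),
                 error = function(e) stop("screen stage (CN): ",
                                          conditionMessage(e),
                                          call. = FALSE))
  km <- tibble::tibble(gene = character(), km_delta_auc = numeric())
  if (nrow(cn) > 0) {
    km <- purrr::map_dfr(cn$gene, function(g) {
      res <- km_delta_auc(cohort, g, split = config$km_split)
      tibble::tibble(gene = g, km_delta_auc = res$delta_auc)
    })
  }
  survivors <- km$gene[km$km_delta_auc < 0]
  funnel_genes <- intersect(survivors, model$genes)
  ots_tables <- purrr::imap(config$mta_datasets, function(pairs, dname) {
    outcomes <- purrr::imap(pairs, function(pair, j) {
      partition <- partition_reactions(pair$source, pair$target, model,
                                       config$params)
      v_ref <- mta_reference_state(model, pair$source,
                                   config$reference_engine)
      ranking <- rank_candidates(model, v_ref, partition,
                                 candidates = model$genes,
                                 params = config$params)
      pair_outcome(ranking, pair_id = paste0(dname, "_pair", j))
    })
    aggregate_ots(outcomes, dataset = dname)
  })
  full_ots <- sum_across_datasets(unname(ots_tables))
  if (length(funnel_genes) == 0) {
    warning("genomic funnel is empty; returning an empty candidate table",
            call. = FALSE)
  }
  report <- full_ots[full_ots$id %in% funnel_genes, , drop = FALSE]
  report <- dplyr::rename(report, gene = "id")
  report <- dplyr::left_join(report,
                             dplyr::select(de, "gene", de_p = "padj"),
                             by = "gene")
  report <- dplyr::left_join(report,
                             dplyr::select(cn, "gene", cn_q = "q"),
                             by = "gene")
  report <- dplyr::left_join(report, km, by = "gene")
  report <- dplyr::arrange(report, dplyr::desc(.data$ots_sum), .data$gene)
  log <- list(
    alpha = config$alpha, q_threshold = config$q_threshold,
    km_split = config$km_split, epsilon = config$params$epsilon,
    alpha_weight = config$params$alpha_weight,
    reference_engine = config$reference_engine, seed = config$seed,
    n_de = nrow(de), n_cn = nrow(cn), n_km = length(survivors),
    n_funnel_model = length(funnel_genes),
    n_datasets = length(config$mta_datasets)
  )
  structure(report, class = c("candidate_table", class(report)),
            log = log, full_ots = full_ots)
}
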