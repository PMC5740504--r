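# MOMA-based phenotype predictions.
#
# MOMA (minimization of metabolic adjustment) predicts the flux state
# after a perturbation as the Euclidean projection of the reference state
# onto the perturbed feasible region. Built on it:
#   * compare_kd_oe: sampled knockdown vs overexpression arms with
#     biomass / glucose / lactate / oxygen read-outs,
#   * flux_change_sets: per-reaction increased/decreased calls after a
#     knockdown, with hypergeometric pathway enrichment,
#   * stage_specific_moma: how close the post-knockout state of each
#     tumor-stage sample comes to the advanced-stage target state,
#   * binomial_validation: the benchmark statistic for top-k retrieval of
#     known knockouts.

#' Minimization of metabolic adjustment
#'
#' Returns `argmin ||v - v_ref||^2` over the perturbed feasible region
#' together with the squared distance.
#'
#' @param model a `metabolic_model`.
#' @param v_ref reference flux (`flux_distribution` or numeric vector).
#' @param knockout optional gene ids to knock out.
#' @param bounds optional tibble `id`, `lb`, `ub` of bound overrides.
#' @return list with `flux` (a `flux_distribution`, provenance `"moma"`)
#'   and `distance` (squared Euclidean adjustment).
#' @export
moma <- function(model, v_ref, knockout = NULL, bounds = NULL) {
  vr <- as_flux_vector(v_ref)
  pert <- model
  if (!is.null(knockout)) pert <- apply_knockout(pert, knockout)
  if (!is.null(bounds)) pert <- set_bounds(pert, bounds)
  p <- model_lp_parts(pert)
  qp <- qp_project(vr, p$Aeq, p$beq, p$lb, p$ub)
  if (is.null(qp)) {
    stop("perturbed model is infeasible; MOMA undefined", call. = FALSE)
  }
  list(flux = flux_distribution(model, qp$v, provenance = "moma"),
       distance = qp$dist2)
}

# Restrict a model to an expression context: reactions whose GPR-mapped
# expression falls below the context threshold are confined to a band
# around their inferred context flux, and (optionally) the biomass lower
# bound is raised to a fraction of its optimum.
context_region <- function(model, expr, engine = c("gimme", "imat"),
                           biomass_fraction = 0, slack = 0.1,
                           objective_fraction = 0.9, threshold = NULL) {
  engine <- match.arg(engine)
  if (engine == "gimme") {
    ref <- gimme(model, expr, threshold = threshold,
                 objective_fraction = objective_fraction)
    thr <- attr(ref, "threshold")
    rx <- reaction_expression(model, as_expr_vector(expr))
    restrict <- which(!is.na(rx$expression) & rx$expression < thr)
  } else {
    calls <- reaction_activity_calls(model, expr)
    ref <- imat(model, calls)
    restrict <- which(calls$call == "low")
  }
  lb <- model$reactions$lb; ub <- model$reactions$ub
  for (i in restrict) {
    band <- abs(ref$v[i]) + slack
    lb[i] <- max(lb[i], -band)
    ub[i] <- min(ub[i], band)
  }
  model$reactions$lb <- lb
  model$reactions$ub <- ub
  if (biomass_fraction > 0) {
    i <- rxn_index(model, model$objective_id)
    opt <- fba(model)$objective_value
    model$reactions$lb[i] <- max(model$reactions$lb[i],
                                 biomass_fraction * opt)
  }
  list(model = model, reference = ref)
}

resolve_readouts <- function(model, readouts) {
  readouts <- readouts %||% model$readouts
  if (is.null(readouts)) {
    stop("no read-out reactions declared; pass `readouts` or build the ",
         "model with a `readouts` map", call. = FALSE)
  }
  rxn_index(model, unname(readouts))  # validates ids
  readouts
}

#' Compare simulated knockdown and overexpression of a gene
#'
#' The wild-type context is inferred with GIMME from `context_expr` and
#' constrained to retain at least `biomass_fraction` of the biomass
#' optimum; `n` wild-type flux states are sampled from it. Each sample is
#' projected by MOMA onto (a) the knockout region (KD arm) and (b) the
#' region where the gene's reactions are forced to at least 80% of their
#' FVA maximum (OE arm). Read-out fluxes are compared between arms with
#' one-sided rank-sum tests in both directions.
#'
#' @param model a `metabolic_model`.
#' @param context_expr expression profile defining the context.
#' @param gene gene id to perturb.
#' @param n flux samples per arm.
#' @param seed integer seed for the sampler.
#' @param biomass_fraction required biomass fraction (default 0.8).
#' @param oe_fraction fraction of the FVA maximum used as the forced
#'   overexpression lower bound (default 0.8).
#' @param readouts named character vector (read-out -> reaction id);
#'   defaults to the model's `readouts` map.
#' @return object of class `phenotype_comparison` with `samples` (tibble:
#'   arm, read-out fluxes) and `tests` (tibble: readout, direction, p).
#' @export
compare_kd_oe <- function(model, context_expr, gene, n = 100, seed = 1,
                          biomass_fraction = 0.8, oe_fraction = 0.8,
                          readouts = NULL) {
  if (!gene %in% model$genes) {
    stop("gene '", gene, "' not in model", call. = FALSE)
  }
  readouts <- resolve_readouts(model, readouts)
  ctx <- context_region(model, context_expr, engine = "gimme")
  # the biomass floor defines the sampled wild-type states only; MOMA
  # projections after the perturbation are free to lose biomass
  wt_sampled <- context_region(model, context_expr, engine = "gimme",
                               biomass_fraction = biomass_fraction)$model
  wt <- ctx$model
  gmap <- gene_reaction_map(wt)
  gene_rxns <- gmap$reaction[gmap$gene == gene]
  blocked <- vapply(rxn_index(wt, gene_rxns), function(i)
    wt$reactions$lb[i] == 0 && wt$reactions$ub[i] == 0, logical(1))
  if (all(blocked)) {
    stop("all reactions of '", gene, "' are blocked in this context",
         call. = FALSE)
  }
  kd_model <- apply_knockout(wt, gene)
  # "maximum" for the forced-overexpression bound: FVA max within the
  # biomass-constrained wild-type region
  vmax <- fva(wt_sampled, reactions = gene_rxns, objective_fraction = 0)
  oe_bounds <- tibble::tibble(
    id = vmax$id,
    lb = pmax(oe_fraction * vmax$max,
              wt$reactions$lb[rxn_index(wt, vmax$id)]),
    ub = wt$reactions$ub[rxn_index(wt, vmax$id)]
  )
  oe_model <- set_bounds(wt, oe_bounds)
  op <- model_lp_parts(oe_model)
  if (!region_feasible(op$Aeq, op$beq, op$lb, op$ub)) {
    stop("overexpression bounds on ", paste(gene_rxns, collapse = ", "),
         " make the model infeasible", call. = FALSE)
  }
  wt_samples <- sample_flux_space(wt_sampled, n = n, seed = seed)
  arm <- function(pert_model, label) {
    purrr::imap_dfr(wt_samples, function(s, i) {
      m <- moma(pert_model, s)
      vals <- m$flux$v[unname(readouts)]
      names(vals) <- names(readouts)
      tibble::as_tibble_row(c(list(arm = label, sample = i),
                              as.list(vals)))
    })
  }
  samples <- dplyr::bind_rows(arm(kd_model, "KD"), arm(oe_model, "OE"))
  tests <- purrr::map_dfr(names(readouts), function(rd) {
    kd <- samples[[rd]][samples$arm == "KD"]
    oe <- samples[[rd]][samples$arm == "OE"]
    safe_p <- function(alt) {
      if (stats::sd(c(kd, oe)) == 0) return(1)
      suppressWarnings(stats::wilcox.test(kd, oe, alternative = alt,
                                          exact = FALSE)$p.value)
    }
    tibble::tibble(readout = rd,
                   direction = c("KD>OE", "OE>KD"),
                   p = c(safe_p("greater"), safe_p("less")))
  })
  structure(list(gene = gene, n = n, samples = samples, tests = tests,
                 readouts = readouts),
            class = "phenotype_comparison")
}

#' @export
print.phenotype_comparison <- function(x, ...) {
  cat("<phenotype_comparison> gene:", x$gene, " n =", x$n, "per arm\n")
  print(x$tests)
  invisible(x)
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a hit set and each pathway, in a fixed universe.
#'
#' @param hits character vector of hit reaction ids.
#' @param pathways named list of reaction id vectors.
#' @param universe character vector of all tested reaction ids.
#' @return tibble `pathway`, `overlap`, `pathway_size`, `hits`, `p`.
#' @export
hypergeometric_enrichment <- function(hits, pathways, universe) {
  hits <- intersect(hits, universe)
  purrr::imap_dfr(pathways, function(rxns, name) {
    K <- length(intersect(rxns, universe))
    k <- length(intersect(intersect(rxns, universe), hits))
    m <- length(hits)
    N <- length(universe)
    p <- if (m == 0 || K == 0) 1
         else stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    tibble::tibble(pathway = name, overlap = k, pathway_size = K,
                   hits = m, p = p)
  })
}

#' Reactions whose flux changes after a knockdown
#'
#' Samples `n` wild-type context states, projects each onto the knockout
#' region with MOMA, and calls each reaction increased / decreased by
#' one-sided rank-sum tests between the two arms at level `alpha`;
#' the increased set is tested for pathway overrepresentation.
#'
#' @inheritParams compare_kd_oe
#' @param alpha per-reaction significance level (default 0.05).
#' @param pathways optional named list of reaction id vectors.
#' @return object of class `flux_change_sets`: per-reaction table,
#'   `increased` / `decreased` id vectors, `enrichment` tibble.
#' @export
flux_change_sets <- function(model, context_expr, gene, n = 100,
                             alpha = 0.05, pathways = NULL, seed = 1,
                             biomass_fraction = 0.8) {
  if (n < 2) stop("need n >= 2 samples", call. = FALSE)
  if (!gene %in% model$genes) {
    stop("gene '", gene, "' not in model", call. = FALSE)
  }
  if (!is.null(pathways)) {
    bad <- setdiff(unlist(pathways), model$reactions$id)
    if (length(bad)) stop("pathway reaction(s) not in model: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  wt <- context_region(model, context_expr, engine = "gimme")$model
  kd_model <- apply_knockout(wt, gene)
  wt_sampled <- context_region(model, context_expr, engine = "gimme",
                               biomass_fraction = biomass_fraction)$model
  wt_samples <- sample_flux_space(wt_sampled, n = n, seed = seed)
  wt_mat <- do.call(rbind, lapply(wt_samples, function(s) s$v))
  kd_mat <- do.call(rbind, lapply(wt_samples, function(s)
    moma(kd_model, s)$flux$v))
  per_rxn <- purrr::map_dfr(seq_len(ncol(wt_mat)), function(i) {
    w <- wt_mat[, i]; k <- kd_mat[, i]
    if (stats::sd(c(w, k)) == 0) {
      return(tibble::tibble(id = model$reactions$id[i], p_inc = 1,
                            p_dec = 1))
    }
    tibble::tibble(
      id = model$reactions$id[i],
      p_inc = suppressWarnings(stats::wilcox.test(
        k, w, alternative = "greater", exact = FALSE)$p.value),
      p_dec = suppressWarnings(stats::wilcox.test(
        k, w, alternative = "less", exact = FALSE)$p.value)
    )
  })
  increased <- per_rxn$id[per_rxn$p_inc < alpha]
  decreased <- setdiff(per_rxn$id[per_rxn$p_dec < alpha], increased)
  enrichment <- if (!is.null(pathways)) {
    hypergeometric_enrichment(increased, pathways, model$reactions$id)
  } else NULL
  structure(list(gene = gene, table = per_rxn, increased = increased,
                 decreased = decreased, enrichment = enrichment,
                 alpha = alpha, n = n),
            class = "flux_change_sets")
}

#' @export
print.flux_change_sets <- function(x, ...) {
  cat("<flux_change_sets> gene:", x$gene, " increased:",
      length(x$increased), " decreased:", length(x$decreased), "\n")
  invisible(x)
}

#' Stage-specific distance to the advanced-tumor state after a knockout
#'
#' Infers the advanced-stage (stage 4) target flux state from the mean
#' stage-4 profile, then, for every sample, infers its post-knockout
#' context state (mean of `n` sampled points in the knocked-out context
#' region, per the chosen engine) and records the squared Euclidean
#' metabolic adjustment to the target. Distances are grouped by stage and
#' compared pairwise with one-sided rank-sum tests (later stage closer).
#'
#' @param model a `metabolic_model`.
#' @param expr genes x samples expression matrix.
#' @param stages vector of stage labels (1-4) aligned to the columns of
#'   `expr` (or named by sample).
#' @param gene gene id to knock out.
#' @param engine `"gimme"` or `"imat"` state-inference engine.
#' @param n sampled points per sample state.
#' @param seed integer seed.
#' @param fdr BH level for the stage-4 down-signature reported alongside.
#' @param gimme_threshold optional absolute expression threshold for the
#'   GIMME context (default: the profile's lower quartile).
#' @param biomass_fraction biomass floor applied to every sample's
#'   context region, modeling proliferating tumor samples (default 0.8).
#' @return object of class `stage_profile`: `distances` tibble (sample,
#'   stage, distance), `tests` tibble, `down_signature` gene vector.
#' @export
stage_specific_moma <- function(model, expr, stages, gene,
                                engine = c("gimme", "imat"), n = 100,
                                seed = 1, fdr = 0.05,
                                gimme_threshold = NULL,
                                biomass_fraction = 0.8) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(expr))
  stages <- as.integer(stages)
  if (!all(1:4 %in% stages)) {
    stop("need at least one sample in every stage 1-4", call. = FALSE)
  }
  s4 <- expr[, stages == 4, drop = FALSE]
  rest <- expr[, stages != 4, drop = FALSE]
  down_sig <- character()
  if (ncol(s4) >= 2 && ncol(rest) >= 2) {
    p <- rowwise_ranksum_less(s4, rest)
    down_sig <- rownames(expr)[stats::p.adjust(p, "BH") < fdr]
  }
  target_profile <- rowMeans(s4)
  # both the per-sample states and the advanced-stage target live on the
  # knocked-out model: the question is how close the post-knockout state
  # of each sample comes to the advanced-stage state
  kd_model <- apply_knockout(model, gene)
  target <- gimme(kd_model, target_profile, threshold = gimme_threshold)
  dist <- purrr::map_dfr(seq_len(ncol(expr)), function(j) {
    prof <- expr[, j]
    ctx <- context_region(kd_model, prof, engine = engine,
                          threshold = gimme_threshold,
                          biomass_fraction = biomass_fraction)
    pts <- sample_flux_space(ctx$model, n = n, seed = seed + j)
    v_mean <- rowMeans(do.call(cbind, lapply(pts, function(s) s$v)))
    tibble::tibble(sample = colnames(expr)[j] %||% paste0("s", j),
                   stage = stages[j],
                   distance = sum((v_mean - target$v)^2))
  })
  tests <- purrr::map_dfr(utils::combn(1:4, 2, simplify = FALSE),
                          function(pr) {
    a <- dist$distance[dist$stage == pr[1]]
    b <- dist$distance[dist$stage == pr[2]]
    p <- if (length(a) < 2 || length(b) < 2 ||
             stats::sd(c(a, b)) == 0) NA_real_
         else suppressWarnings(stats::wilcox.test(
           a, b, alternative = "greater", exact = FALSE)$p.value)
    tibble::tibble(stage_a = pr[1], stage_b = pr[2],
                   direction = "a_farther", p = p)
  })
  structure(list(gene = gene, engine = engine, distances = dist,
                 tests = tests, down_signature = down_sig),
            class = "stage_profile")
}

#' @export
print.stage_profile <- function(x, ...) {
  cat("<stage_profile> gene:", x$gene, " engine:", x$engine, "\n")
  meds <- dplyr::summarise(dplyr::group_by(x$distances, .data$stage),
                           median = stats::median(.data$distance),
                           .groups = "drop")
  print(meds)
  invisible(x)
}

#' Binomial benchmark statistic
#'
#' Probability model for recovering known knockouts in the top fraction
#' of a ranking: `point` returns the binomial mass at exactly
#' `successes`, `tail` the probability of at least `successes`.
#'
#' @param successes,trials non-negative counts, `successes <= trials`.
#' @param rate success probability per trial (e.g. 0.2 for a top-20%
#'   criterion).
#' @param mode `"point"` or `"tail"`.
#' @return probability.
#' @export
binomial_validation <- function(successes, trials, rate = 0.2,
                                mode = c("point", "tail")) {
  mode <- match.arg(mode)
  if (successes < 0 || trials < 0 || successes > trials) {
    stop("need 0 <= successes <= trials", call. = FALSE)
  }
  if (rate <= 0 || rate >= 1) stop("rate must be in (0, 1)", call. = FALSE)
  if (mode == "point") stats::dbinom(successes, trials, rate)
  else stats::pbinom(successes - 1, trials, rate, lower.tail = FALSE)
}
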