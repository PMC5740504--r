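# The metabolic transformation algorithm (MTA).
#
# Given a source metabolic state (a reference flux distribution inferred
# from source expression) and target expression, MTA asks which single
# gene knockout moves the flux distribution toward the target state. The
# pipeline is:
#   1. partition reactions by the expression change between source and
#      target into R_F (must increase), R_B (must decrease) and R_S
#      (should stay);
#   2. for each candidate knockout, solve a mixed-integer quadratic
#      program: maximise  alpha * (# achieved changes)
#                        - (1 - alpha) * sum_{R_S} (v - v_ref)^2
#      over the knocked-out flux polytope, with a binary per R_F/R_B
#      reaction indicating whether it moved by at least epsilon in the
#      required direction;
#   3. score the resulting flux vector v_res with the transformation
#      score TS = [sum_{R_success}|dv| - sum_{R_unsuccess}|dv|] /
#      sum_{R_S}|dv|, where the success sets are re-derived post hoc from
#      v_res (not taken from the binaries) — a deliberately two-step
#      design, because the integer objective cannot distinguish barely
#      epsilon-crossing changes from large ones;
#   4. rank candidates by TS, always including the no-perturbation
#      control.
# The MIQP is solved by depth-first branch-and-bound over the success
# binaries; node relaxations are strictly convex QPs, so bounds are exact
# and the search is deterministic.

#' MTA tuning parameters
#'
#' @param epsilon minimal flux change (flux units) that counts as a
#'   successful directional change.
#' @param alpha_weight weight of the integer term in the MIQP objective
#'   (the quadratic stay-close term gets `1 - alpha_weight`).
#' @param significance level for gene differential-expression calls in
#'   [partition_reactions()].
#' @param lfc_threshold absolute log2 fold-change cut used when only one
#'   sample per side is available.
#' @param max_nodes branch-and-bound node budget per candidate; exceeding
#'   it yields status `"timeout"` with the incumbent solution.
#' @return list of class `mta_params`.
#' @export
mta_params <- function(epsilon = 0.1, alpha_weight = 0.66,
                       significance = 0.05, lfc_threshold = 1,
                       max_nodes = 1e5) {
  stopifnot(epsilon > 0, alpha_weight > 0, alpha_weight < 1)
  structure(list(epsilon = epsilon, alpha_weight = alpha_weight,
                 significance = significance,
                 lfc_threshold = lfc_threshold, max_nodes = max_nodes),
            class = "mta_params")
}

as_profile_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) || (is.numeric(x) && !is.null(names(x)))) {
    v <- as_expr_vector(x)
    return(matrix(v, ncol = 1, dimnames = list(names(v), NULL)))
  }
  if (is.list(x)) {
    vs <- lapply(x, as_expr_vector)
    genes <- names(vs[[1]])
    stopifnot(all(vapply(vs, function(v) identical(names(v), genes),
                         logical(1))))
    return(do.call(cbind, vs))
  }
  stop("cannot interpret expression input", call. = FALSE)
}

#' Partition reactions by expression change between two states
#'
#' Genes are called up/down/unchanged between source and target; with
#' replicates a two-sided rank-sum test at `params$significance` with BH
#' correction is used, with single paired samples an absolute log2
#' fold-change threshold. Calls propagate to reactions through the GPR:
#' a reaction with at least one up-called gene and no down-called gene
#' joins R_F (required flux increase), the mirror case joins R_B, and
#' conflicting or silent reactions stay in R_S.
#'
#' @param source_samples,target_samples expression input: a named vector,
#'   `gene`/`value` tibble, list of profiles, or genes x samples matrix.
#' @param model a `metabolic_model`.
#' @param params an [mta_params()] object.
#' @return object of class `reaction_partition` with elements `rf`, `rb`,
#'   `rs` (reaction id vectors) and `gene_calls` (tibble).
#' @export
partition_reactions <- function(source_samples, target_samples, model,
                                params = mta_params()) {
  src <- as_profile_matrix(source_samples)
  tgt <- as_profile_matrix(target_samples)
  genes <- intersect(intersect(rownames(src), rownames(tgt)), model$genes)
  if (length(genes) == 0) {
    stop("expression data shares no genes with the model", call. = FALSE)
  }
  src <- src[genes, , drop = FALSE]
  tgt <- tgt[genes, , drop = FALSE]
  if (ncol(src) >= 2 && ncol(tgt) >= 2) {
    pvals <- vapply(genes, function(g) {
      if (stats::sd(c(src[g, ], tgt[g, ])) == 0) return(1)
      suppressWarnings(
        stats::wilcox.test(tgt[g, ], src[g, ], exact = FALSE)$p.value)
    }, numeric(1))
    padj <- stats::p.adjust(pvals, method = "BH")
    delta <- apply(tgt, 1, stats::median) - apply(src, 1, stats::median)
    call <- ifelse(padj < params$significance & delta > 0, "up",
                   ifelse(padj < params$significance & delta < 0, "down",
                          "unchanged"))
  } else {
    # moderated pseudo-count keeps near-silent genes from producing
    # spurious huge fold changes
    pc <- 0.5
    s1 <- pmax(rowMeans(src), 0) + pc
    t1 <- pmax(rowMeans(tgt), 0) + pc
    lfc <- log2(t1 / s1)
    call <- ifelse(lfc >= params$lfc_threshold, "up",
                   ifelse(lfc <= -params$lfc_threshold, "down",
                          "unchanged"))
    padj <- rep(NA_real_, length(genes))
  }
  gene_calls <- tibble::tibble(gene = genes, call = unname(call),
                               padj = unname(padj))
  up_genes <- gene_calls$gene[gene_calls$call == "up"]
  down_genes <- gene_calls$gene[gene_calls$call == "down"]
  rxn_call <- vapply(model$reactions$id, function(r) {
    g <- gpr_genes(model$gpr[[r]])
    has_up <- any(g %in% up_genes)
    has_down <- any(g %in% down_genes)
    if (has_up && !has_down) "rf"
    else if (has_down && !has_up) "rb"
    else "rs"
  }, character(1))
  structure(list(
    rf = model$reactions$id[rxn_call == "rf"],
    rb = model$reactions$id[rxn_call == "rb"],
    rs = model$reactions$id[rxn_call == "rs"],
    gene_calls = gene_calls
  ), class = "reaction_partition")
}

#' @export
print.reaction_partition <- function(x, ...) {
  cat("<reaction_partition> R_F:", length(x$rf), " R_B:", length(x$rb),
      " R_S:", length(x$rs), "\n")
  invisible(x)
}

#' Manually build a reaction partition
#' @param rf,rb,rs reaction id vectors (disjoint; union = all reactions).
#' @return a `reaction_partition`.
#' @export
reaction_partition <- function(rf, rb, rs) {
  if (anyDuplicated(c(rf, rb, rs))) {
    stop("R_F, R_B, R_S must be disjoint", call. = FALSE)
  }
  structure(list(rf = rf, rb = rb, rs = rs, gene_calls = NULL),
            class = "reaction_partition")
}

as_flux_vector <- function(x) {
  if (inherits(x, "flux_distribution")) x$v else x
}

#' Transformation score (TS)
#'
#' `TS = [sum_{R_success} |dv| - sum_{R_unsuccess} |dv|] / sum_{R_S} |dv|`
#' where `dv = v_res - v_ref` and `R_success` are the R_F/R_B reactions
#' whose flux moved by at least `epsilon` in the required direction.
#' Degenerate denominators below `1e-9` fall back to dividing by `1e-9`
#' with the result capped at `+/-1e9`; when the numerator is also below
#' `1e-9` in magnitude the score is 0 (so a null perturbation scores 0).
#'
#' @param v_ref,v_res reference and perturbed flux vectors
#'   (`flux_distribution` or named numeric aligned to the model).
#' @param partition a `reaction_partition`.
#' @param epsilon success threshold (flux units).
#' @return scalar score, with attributes `success`/`unsuccess` listing the
#'   reaction ids.
#' @export
transformation_score <- function(v_ref, v_res, partition, epsilon = 0.1) {
  vr <- as_flux_vector(v_ref); vs <- as_flux_vector(v_res)
  if (length(vr) != length(vs)) {
    stop("flux vectors have different lengths", call. = FALSE)
  }
  dv <- vs - vr
  succ_f <- partition$rf[dv[partition$rf] >= epsilon]
  succ_b <- partition$rb[dv[partition$rb] <= -epsilon]
  success <- c(succ_f, succ_b)
  unsuccess <- setdiff(c(partition$rf, partition$rb), success)
  num <- sum(abs(dv[success])) - sum(abs(dv[unsuccess]))
  den <- sum(abs(dv[partition$rs]))
  delta <- 1e-9
  ts <- if (den < delta) {
    if (abs(num) < delta) 0 else max(min(num / delta, 1e9), -1e9)
  } else {
    num / den
  }
  attr(ts, "success") <- success
  attr(ts, "unsuccess") <- unsuccess
  ts
}

#' Solve the MTA transformation search for one candidate knockout
#'
#' Applies the knockout, then maximises
#' `alpha * #{achieved changes} - (1 - alpha) * sum_{R_S} (v - v_ref)^2`
#' by branch-and-bound over the binary success indicators (R_F success:
#' `v >= v_ref + epsilon`; R_B success: `v <= v_ref - epsilon`). Node
#' relaxations are strictly convex QPs; infeasible partial assignments and
#' nodes whose attainable objective cannot beat the incumbent are pruned.
#'
#' @param model a `metabolic_model`.
#' @param v_ref reference (source-state) flux distribution.
#' @param partition a `reaction_partition`.
#' @param candidate gene id, or `"control"` for the unperturbed model.
#' @param params an [mta_params()] object.
#' @return object of class `mta_result`: candidate, `v_res`, achieved
#'   success/unsuccess sets, `ts`, MIQP objective, status.
#' @export
solve_mta <- function(model, v_ref, partition, candidate = "control",
                      params = mta_params()) {
  vr <- as_flux_vector(v_ref)
  ko_model <- if (identical(candidate, "control")) model
              else apply_knockout(model, candidate)
  p <- model_lp_parts(ko_model)
  n <- length(p$lb)
  eps <- params$epsilon
  alpha <- params$alpha_weight
  rs_idx <- rxn_index(model, partition$rs)
  wts <- rep(1e-6, n)       # tiny ridge keeps the QP strictly convex
  wts[rs_idx] <- 1
  cand_ids <- c(partition$rf, partition$rb)
  cand_idx <- rxn_index(model, cand_ids)
  dir <- c(rep(1, length(partition$rf)), rep(-1, length(partition$rb)))
  ord <- order(cand_ids)
  cand_ids <- cand_ids[ord]; cand_idx <- cand_idx[ord]; dir <- dir[ord]
  if (!region_feasible(p$Aeq, p$beq, p$lb, p$ub)) {
    res <- structure(list(candidate = candidate, v_res = NULL,
                          success = character(), unsuccess = cand_ids,
                          ts = -1e9, objective = NA_real_,
                          miqp_success_count = 0L,
                          status = "infeasible"),
                     class = "mta_result")
    return(res)
  }
  dist_rs <- function(v) sum((v[rs_idx] - vr[rs_idx])^2)
  # success constraint rows, expressed as Ain v <= bin
  row_for <- function(j) {
    r <- cand_idx[j]
    a <- numeric(n)
    if (dir[j] > 0) { a[r] <- -1; b <- -(vr[r] + eps) }
    else            { a[r] <-  1; b <-   vr[r] - eps }
    list(a = a, b = b)
  }
  best <- new.env(parent = emptyenv())
  best$obj <- -Inf; best$k <- -1L; best$v <- NULL
  nodes <- 0L; budget_hit <- FALSE
  recurse <- function(j, Ain, bin, k) {
    nodes <<- nodes + 1L
    if (nodes > params$max_nodes) { budget_hit <<- TRUE; return() }
    qp <- qp_project(vr, p$Aeq, p$beq, p$lb, p$ub,
                     Ain = if (is.null(Ain)) NULL else Ain, bin = bin,
                     weights = wts)
    if (is.null(qp)) return()
    remaining <- length(cand_idx) - j + 1L
    # qp$dist2 lower-bounds the weighted stay-term of any completion;
    # the ridge contribution is subtracted before using it as a bound
    lower_stay <- max(qp$dist2 - 1e-6 * sum((qp$v - vr)^2), 0)
    bound <- alpha * (k + remaining) - (1 - alpha) * lower_stay
    if (bound <= best$obj + 1e-9) return()
    if (j > length(cand_idx)) {
      obj <- alpha * k - (1 - alpha) * dist_rs(qp$v)
      if (obj > best$obj + 1e-9 ||
          (obj > best$obj - 1e-9 && k > best$k)) {
        best$obj <- obj; best$k <- k; best$v <- qp$v
      }
      return()
    }
    rr <- row_for(j)
    recurse(j + 1L, rbind(Ain, rr$a), c(bin, rr$b), k + 1L)  # success first
    recurse(j + 1L, Ain, bin, k)
  }
  recurse(1L, NULL, NULL, 0L)
  status <- if (budget_hit) "timeout" else "optimal"
  v_res <- best$v
  if (is.null(v_res)) {  # budget exhausted before any leaf
    qp <- qp_project(vr, p$Aeq, p$beq, p$lb, p$ub, weights = wts)
    v_res <- qp$v
    best$k <- 0L
  }
  ts <- transformation_score(vr, v_res, partition, epsilon = eps)
  structure(list(
    candidate = candidate,
    v_res = flux_distribution(model, v_res, provenance = "mta"),
    success = attr(ts, "success"),
    unsuccess = attr(ts, "unsuccess"),
    ts = as.numeric(ts),
    objective = best$obj,
    miqp_success_count = best$k,
    status = status
  ), class = "mta_result")
}

#' @export
print.mta_result <- function(x, ...) {
  cat("<mta_result> candidate:", x$candidate, " ts:",
      format(x$ts, digits = 5), " achieved:", length(x$success), "/",
      length(x$success) + length(x$unsuccess), " (", x$status, ")\n")
  invisible(x)
}

#' Rank candidate knockouts by transformation score
#'
#' Runs [solve_mta()] for every candidate gene plus the no-perturbation
#' control, and ranks by TS (descending; ties broken lexicographically by
#' candidate id). Percentile ranks are reported over the gene candidates
#' (control excluded): the top gene gets `100 / n_genes`.
#'
#' @param model a `metabolic_model`.
#' @param v_ref reference flux distribution.
#' @param partition a `reaction_partition`.
#' @param candidates character vector of gene ids (non-empty).
#' @param params an [mta_params()] object.
#' @return tibble of class `mta_ranking`: `candidate`, `ts`, `n_success`,
#'   `status`, `is_control`, `percentile`.
#' @export
rank_candidates <- function(model, v_ref, partition, candidates,
                            params = mta_params()) {
  candidates <- setdiff(unique(candidates), "control")
  if (length(candidates) == 0) {
    stop("no candidate genes supplied", call. = FALSE)
  }
  unknown <- setdiff(candidates, model$genes)
  if (length(unknown)) {
    stop("candidate(s) not in model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  results <- lapply(c("control", sort(candidates)), function(g)
    solve_mta(model, v_ref, partition, g, params))
  tab <- purrr::map_dfr(results, function(r) tibble::tibble(
    candidate = r$candidate, ts = r$ts,
    n_success = length(r$success), status = r$status,
    is_control = identical(r$candidate, "control")
  ))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$ts), .data$candidate)
  genes_only <- tab$candidate[!tab$is_control]
  pos <- match(tab$candidate, genes_only)
  tab$percentile <- 100 * pos / length(genes_only)
  out <- structure(tab, class = c("mta_ranking", class(tab)))
  attr(out, "params") <- params
  attr(out, "control_ts") <- tab$ts[tab$is_control]
  out
}
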