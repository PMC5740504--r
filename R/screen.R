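# Step-one genomic screen.
#
# Candidate metabolic tumor suppressors are funnelled through three
# sequential filters on a tumor/normal cohort:
#   (i)  genes significantly *down* in tumors (one-sided rank-sum,
#        BH-corrected p < alpha, default 0.001),
#   (ii) of those, genes with significantly *lower copy number* in tumors
#        (one-sided rank-sum, BH Q-value < 0.25),
#   (iii) of those, genes whose low expression associates with poor
#        survival: Kaplan-Meier curve area difference
#        dAUC = AUC(low) - AUC(high) < 0.
# Plus two supporting utilities: reference-distribution quantile
# normalization and Spearman correlation between copy-number profiles.

#' Assemble a cohort table
#'
#' @param expr genes x samples expression matrix (rownames = genes).
#' @param samples tibble with columns `sample`, `group`
#'   (`"tumor"`/`"normal"`) and optionally `stage`, `pair_id`.
#' @param cn optional genes x samples copy-number matrix.
#' @param survival optional tibble `sample`, `time` (days), `event` (0/1).
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(expr, samples, cn = NULL, survival = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample", "group") %in% names(samples)))
  stopifnot(setequal(colnames(expr), samples$sample))
  if (!is.null(cn)) {
    stopifnot(is.matrix(cn), all(colnames(cn) %in% samples$sample))
  }
  if (!is.null(survival)) {
    survival <- tibble::as_tibble(survival)
    stopifnot(all(c("sample", "time", "event") %in% names(survival)))
    stopifnot(all(survival$time >= 0), all(survival$event %in% c(0, 1)))
    stopifnot(all(survival$sample %in% samples$sample))
  }
  structure(list(expr = expr, cn = cn, survival = survival,
                 samples = samples),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$expr), " genes x ", ncol(x$expr),
      " samples (", sum(x$samples$group == "tumor"), " tumor / ",
      sum(x$samples$group == "normal"), " normal); CN: ",
      !is.null(x$cn), "; survival: ", !is.null(x$survival), "\n", sep = "")
  invisible(x)
}

cohort_groups <- function(cohort) {
  list(tumor = cohort$samples$sample[cohort$samples$group == "tumor"],
       normal = cohort$samples$sample[cohort$samples$group == "normal"])
}

rowwise_ranksum_less <- function(mat_t, mat_n) {
  # one-sided (tumor < normal) Wilcoxon rank-sum per row, normal
  # approximation with continuity correction (standard for large screens)
  vapply(seq_len(nrow(mat_t)), function(i) {
    x <- mat_t[i, ]; y <- mat_n[i, ]
    if (stats::sd(c(x, y)) == 0) return(1)
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "less",
                         exact = FALSE)$p.value)
  }, numeric(1))
}

#' Differential-expression screen (tumor below normal)
#'
#' @param cohort a [cohort_table()].
#' @param alpha BH-corrected significance level (default 0.001).
#' @return tibble `gene`, `p`, `padj` for the genes passing the screen.
#' @export
diff_expr_screen <- function(cohort, alpha = 0.001) {
  g <- cohort_groups(cohort)
  if (length(g$tumor) < 2 || length(g$normal) < 2) {
    stop("need at least two samples per group", call. = FALSE)
  }
  p <- rowwise_ranksum_less(cohort$expr[, g$tumor, drop = FALSE],
                            cohort$expr[, g$normal, drop = FALSE])
  padj <- stats::p.adjust(p, method = "BH")
  tab <- tibble::tibble(gene = rownames(cohort$expr), p = p, padj = padj)
  dplyr::arrange(tab[tab$padj < alpha, ], .data$padj)
}

#' Copy-number deletion screen
#'
#' @param cohort a [cohort_table()] with a CN block.
#' @param q_threshold BH Q-value threshold (default 0.25).
#' @param genes optional restriction (e.g. the DE screen's output).
#' @return tibble `gene`, `p`, `q` for genes with significantly lower
#'   tumor copy number.
#' @export
cn_screen <- function(cohort, q_threshold = 0.25, genes = NULL) {
  if (is.null(cohort$cn)) stop("cohort has no copy-number block",
                               call. = FALSE)
  g <- cohort_groups(cohort)
  g$tumor <- intersect(g$tumor, colnames(cohort$cn))
  g$normal <- intersect(g$normal, colnames(cohort$cn))
  if (length(g$tumor) < 2 || length(g$normal) < 2) {
    stop("need at least two CN samples per group", call. = FALSE)
  }
  cn <- cohort$cn
  if (!is.null(genes)) cn <- cn[intersect(genes, rownames(cn)), ,
                                drop = FALSE]
  p <- rowwise_ranksum_less(cn[, g$tumor, drop = FALSE],
                            cn[, g$normal, drop = FALSE])
  q <- stats::p.adjust(p, method = "BH")
  tab <- tibble::tibble(gene = as.character(rownames(cn) %||% character()),
                        p = p, q = q)
  dplyr::arrange(tab[tab$q < q_threshold, ], .data$q)
}

km_curve_auc <- function(time, event, horizon) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  t <- c(0, fit$time)
  s <- c(1, fit$surv)
  area <- 0
  for (i in seq_along(fit$time)) {
    lo <- min(t[i], horizon); hi <- min(t[i + 1], horizon)
    area <- area + s[i] * (hi - lo)
  }
  if (horizon > max(t)) area <- area + s[length(s)] * (horizon - max(t))
  area
}

#' Kaplan-Meier curve-area difference for one gene
#'
#' Splits the surviving samples into low/high expression bins, fits a
#' Kaplan-Meier estimator per bin, and integrates both step functions up
#' to a common horizon. `delta_auc = AUC(low) - AUC(high)`; negative
#' values mean low expression tracks poorer survival.
#'
#' @param cohort a [cohort_table()] with a survival block.
#' @param gene gene id.
#' @param split `"median"` (ties at the median go to the low bin) or
#'   `"quartiles"` (bottom vs top quartile, middle half dropped).
#' @param horizon integration horizon in time units; default `NULL` uses
#'   the smaller of the two bins' last observed times, so neither curve is
#'   extrapolated.
#' @return object of class `km_result` with `delta_auc`, bin sizes,
#'   horizon, and the per-bin survfit objects.
#' @export
km_delta_auc <- function(cohort, gene, split = c("median", "quartiles"),
                         horizon = NULL) {
  split <- match.arg(split)
  if (is.null(cohort$survival)) stop("cohort has no survival block",
                                     call. = FALSE)
  if (!gene %in% rownames(cohort$expr)) {
    stop("gene '", gene, "' not in expression matrix", call. = FALSE)
  }
  surv <- cohort$survival
  expr <- cohort$expr[gene, surv$sample]
  if (split == "median") {
    med <- stats::median(expr)
    low <- expr <= med
    high <- !low
    if (!any(high)) {
      stop("degenerate split: all samples tied at the median for '",
           gene, "'", call. = FALSE)
    }
  } else {
    qs <- stats::quantile(expr, c(0.25, 0.75))
    low <- expr <= qs[1]
    high <- expr >= qs[2]
  }
  if (sum(low) < 2 || sum(high) < 2) {
    stop("degenerate split: fewer than two samples in a bin for '",
         gene, "'", call. = FALSE)
  }
  t_low <- surv$time[low]; e_low <- surv$event[low]
  t_high <- surv$time[high]; e_high <- surv$event[high]
  if (is.null(horizon)) horizon <- min(max(t_low), max(t_high))
  auc_low <- km_curve_auc(t_low, e_low, horizon)
  auc_high <- km_curve_auc(t_high, e_high, horizon)
  structure(list(
    gene = gene, split = split,
    delta_auc = auc_low - auc_high,
    auc_low = auc_low, auc_high = auc_high,
    horizon = horizon, n_low = sum(low), n_high = sum(high),
    fit_low = survival::survfit(survival::Surv(t_low, e_low) ~ 1),
    fit_high = survival::survfit(survival::Surv(t_high, e_high) ~ 1)
  ), class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result> ", x$gene, " (", x$split, " split): dAUC = ",
      format(x$delta_auc, digits = 5), " over horizon ", x$horizon,
      " (n_low = ", x$n_low, ", n_high = ", x$n_high, ")\n", sep = "")
  invisible(x)
}

#' Quantile normalization against a reference distribution
#'
#' Each column's values are replaced rank-wise by the sorted reference
#' distribution (ties receive the average of the tied reference values),
#' so every column has exactly the reference distribution while keeping
#' its within-sample rank order.
#'
#' @param mat genes x samples matrix.
#' @param reference per-gene reference values; defaults to the mean
#'   expression of each gene across samples, `rowMeans(mat)`.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat, reference = rowMeans(mat)) {
  if (length(reference) != nrow(mat)) {
    stop("reference length ", length(reference), " != gene count ",
         nrow(mat), call. = FALSE)
  }
  sr <- sort(reference)
  out <- apply(mat, 2, function(x) {
    r <- rank(x, ties.method = "average")
    (sr[floor(r)] + sr[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Spearman correlation between two genes' copy-number profiles
#'
#' @param cohort a [cohort_table()] with a CN block.
#' @param gene_a,gene_b gene ids present in the CN matrix.
#' @return tibble `gene_a`, `gene_b`, `rho`, `p` (two-sided).
#' @export
marker_correlation <- function(cohort, gene_a, gene_b) {
  if (is.null(cohort$cn)) stop("cohort has no copy-number block",
                               call. = FALSE)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(cohort$cn)) {
      stop("gene '", g, "' not in CN matrix", call. = FALSE)
    }
  }
  a <- cohort$cn[gene_a, ]; b <- cohort$cn[gene_b, ]
  if (length(a) < 4) stop("need at least 4 samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: constant copy-number vector",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE))
  tibble::tibble(gene_a = gene_a, gene_b = gene_b,
                 rho = unname(ct$estimate), p = ct$p.value)
}
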