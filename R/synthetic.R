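# Synthetic data with implanted ground truth.
#
# Three generators make every pipeline stage testable without external
# data:
#   * make_toy_model: a small branched network (glucose uptake ->
#     glycolysis -> an oxidative route vs fermentative branches -> biomass,
#     plus inert side modules) in which one gene is an implanted causal
#     driver: its reaction carries an obligatory minimum flux, so only its
#     knockout can reroute carbon into the designated fermentative
#     target reactions;
#   * generate_paired_expression: matched source/target profiles derived
#     from the wild-type and knocked-out flux states (expression =
#     GPR-propagated absolute flux plus Gaussian noise), emulating paired
#     healthy/tumor transcriptomes;
#   * generate_cohort: tumor/normal expression, copy-number and survival
#     blocks where the driver is down-shifted, focally deleted, and its
#     low expression carries an elevated exponential hazard.
# Every generator is a pure function of (parameters, seed).

#' Ground-truth record for synthetic artifacts
#'
#' @param driver_gene implanted driver gene id (`NA` for null data).
#' @param expr_shift tumor expression shift of the driver, in within-group
#'   standard deviations (negative = downregulated).
#' @param cn_loss_fraction fraction of tumors carrying the focal deletion.
#' @param hazard_ratio hazard multiplier for tumors with below-median
#'   driver expression (> 0).
#' @param seed integer seed recorded with the artifact.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(driver_gene = "gDRV", expr_shift = -3,
                            cn_loss_fraction = 0.6, hazard_ratio = 2,
                            seed = 1) {
  stopifnot(hazard_ratio > 0, cn_loss_fraction >= 0, cn_loss_fraction <= 1)
  structure(list(driver_gene = driver_gene, expr_shift = expr_shift,
                 cn_loss_fraction = cn_loss_fraction,
                 hazard_ratio = hazard_ratio, seed = seed,
                 rf_reactions = character()),
            class = "synthetic_truth")
}

#' Build a toy metabolic network with an implanted driver
#'
#' Glucose is taken up and split to pyruvate; an oxidative reaction
#' (`OXID`, gene `gDRV`) converts pyruvate efficiently (2 energy units,
#' consuming oxygen) while `n_branches` fermentative branches (`FERM_i`,
#' isozyme pairs) yield less energy and secrete lactate. With
#' `with_driver`, `OXID` carries an obligatory minimum flux just under
#' the full pyruvate supply, so the fermentative branches (the designated
#' target set) can only light up when `gDRV` is knocked out — the
#' implanted causal driver event. Side modules (a glutamine shuttle, a
#' free respiration sink, a permanently blocked reaction) provide inert
#' candidate genes.
#'
#' @param n_branches number of fermentative branches (>= 2).
#' @param with_driver implant the driver construction (otherwise the
#'   oxidative route is absent and no knockout reroutes flux).
#' @param seed integer seed (perturbs capacities).
#' @return list with elements `model` (a `metabolic_model`) and `truth`
#'   (a [synthetic_truth()] whose `rf_reactions` name the reactions a
#'   driver knockout must increase).
#' @export
make_toy_model <- function(n_branches = 3, with_driver = TRUE, seed = 1) {
  stopifnot(n_branches >= 2)
  caps <- withr::with_seed(seed, {
    list(glc = stats::runif(1, 9, 11),
         ferm = stats::runif(n_branches, 7, 9))
  })
  pyr_supply <- 2 * caps$glc
  margin <- 0.05  # obligatory-flux slack left for the control
  mets <- tibble::tibble(
    id = c("glc", "pyr", "nrg", "lac", "o2", "gln", "aux", "zzz"),
    compartment = "c"
  )
  ferm_ids <- paste0("FERM", seq_len(n_branches))
  rxns <- tibble::tibble(
    id = c("EX_glc", "EX_o2", "EX_lac", "EX_gln", "EX_aux",
           "GLYC", "OXID", ferm_ids, "RESP", "AUXR", "ZRXN", "BIOMASS"),
    lb = c(-caps$glc, -20, 0, -5, 0,
           0, if (with_driver) pyr_supply - margin else 0,
           rep(0, n_branches), 0, 0, 0, 0),
    ub = c(0, 0, 1000, 0, 1000,
           1000, if (with_driver) 1000 else 0,
           caps$ferm, 20, 1000, 10, 1000),
    gpr = c("", "", "", "", "",
            "gGLYC1 and gGLYC2", "gDRV",
            paste0("gFA", seq_len(n_branches), " or gFB",
                   seq_len(n_branches)),
            "gRESP", "gAUX1 and gAUX2", "gZRO", "")
  )
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  S["glc", "EX_glc"] <- -1
  S["o2", "EX_o2"] <- -1
  S["lac", "EX_lac"] <- -1
  S["gln", "EX_gln"] <- -1
  S["aux", "EX_aux"] <- -1
  S["glc", "GLYC"] <- -1; S["pyr", "GLYC"] <- 2
  S["pyr", "OXID"] <- -1; S["o2", "OXID"] <- -0.2; S["nrg", "OXID"] <- 2
  for (f in ferm_ids) {
    S["pyr", f] <- -1; S["nrg", f] <- 1.5; S["lac", f] <- 0.1
  }
  S["o2", "RESP"] <- -1
  S["gln", "AUXR"] <- -1; S["aux", "AUXR"] <- 1
  S["zzz", "ZRXN"] <- -1
  S["nrg", "BIOMASS"] <- -1
  model <- metabolic_model(
    mets, rxns, S,
    objective_id = "BIOMASS",
    exchange_ids = c("EX_glc", "EX_o2", "EX_lac", "EX_gln", "EX_aux"),
    readouts = c(biomass = "BIOMASS", glucose = "EX_glc",
                 lactate = "EX_lac", oxygen = "EX_o2")
  )
  truth <- synthetic_truth(
    driver_gene = if (with_driver) "gDRV" else NA_character_,
    seed = seed
  )
  if (with_driver) truth$rf_reactions <- ferm_ids
  list(model = model, truth = truth)
}

gene_expression_from_flux <- function(model, v, floor_value = 0.05) {
  gmap <- gene_reaction_map(model)
  vals <- vapply(model$genes, function(g) {
    rxns <- gmap$reaction[gmap$gene == g]
    max(abs(v[rxns]))
  }, numeric(1))
  pmax(vals, floor_value)
}

#' Paired source/target expression profiles from a toy model
#'
#' Source profiles reflect the wild-type flux state, target profiles the
#' driver-knockout state (with the driver gene's own expression pinned to
#' the floor value): each gene's expression is the maximum absolute flux
#' over its reactions plus Gaussian noise, truncated at zero.
#'
#' @param model toy `metabolic_model` from [make_toy_model()].
#' @param truth the matching [synthetic_truth()].
#' @param n_pairs number of matched pairs.
#' @param noise_sd Gaussian noise standard deviation (expression units).
#' @param seed integer seed.
#' @param floor_value expression floor for silent genes.
#' @return list of `n_pairs` lists with elements `source` and `target`
#'   (tibbles `gene`, `value`); the truth is attached as an attribute.
#' @export
generate_paired_expression <- function(model, truth, n_pairs = 10,
                                       noise_sd = 0.2, seed = 1,
                                       floor_value = 0.05) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.na(truth$driver_gene))
  v_wt <- fba(model)$v
  v_ko <- fba(apply_knockout(model, truth$driver_gene))$v
  base_src <- gene_expression_from_flux(model, v_wt, floor_value)
  base_tgt <- gene_expression_from_flux(model, v_ko, floor_value)
  base_tgt[truth$driver_gene] <- floor_value
  pairs <- withr::with_seed(seed, {
    lapply(seq_len(n_pairs), function(j) {
      noise <- function(base) {
        x <- base + stats::rnorm(length(base), 0, noise_sd)
        pmax(x, 0)
      }
      s <- if (noise_sd > 0) noise(base_src) else base_src
      t <- if (noise_sd > 0) noise(base_tgt) else base_tgt
      t[truth$driver_gene] <- if (noise_sd > 0)
        max(floor_value + stats::rnorm(1, 0, noise_sd / 10), 0)
      else floor_value
      list(source = tibble::tibble(gene = model$genes,
                                   value = unname(s)),
           target = tibble::tibble(gene = model$genes,
                                   value = unname(t)))
    })
  })
  attr(pairs, "truth") <- truth
  pairs
}

#' Synthetic tumor/normal cohort with survival
#'
#' Nuisance genes are exchangeable between groups; the driver is
#' down-shifted in tumors by `truth$expr_shift` within-group standard
#' deviations, focally deleted (one copy lost) in
#' `truth$cn_loss_fraction` of tumors, and below-median driver expression
#' multiplies the exponential death hazard by `truth$hazard_ratio`.
#' Censoring is uniform over the follow-up horizon.
#'
#' @param truth a [synthetic_truth()].
#' @param n_tumor,n_normal sample counts (>= 10 each).
#' @param seed integer seed.
#' @param gene_ids gene universe; defaults to the driver plus
#'   `n_nuisance` nuisance genes.
#' @param n_nuisance number of no-effect genes when `gene_ids` is NULL.
#' @param base_median_survival median survival of the baseline group
#'   (days).
#' @param horizon censoring horizon (days).
#' @return a [cohort_table()]; the truth is attached as an attribute.
#' @export
generate_cohort <- function(truth, n_tumor = 272, n_normal = 42, seed = 1,
                            gene_ids = NULL, n_nuisance = 200,
                            base_median_survival = 1000, horizon = 2500) {
  stopifnot(inherits(truth, "synthetic_truth"),
            n_tumor >= 10, n_normal >= 10)
  has_driver <- !is.na(truth$driver_gene)
  if (is.null(gene_ids)) {
    gene_ids <- c(if (has_driver) truth$driver_gene,
                  sprintf("nuis%03d", seq_len(n_nuisance)))
  }
  gene_ids <- unique(gene_ids)
  out <- withr::with_seed(seed, {
    ng <- length(gene_ids)
    mu <- stats::runif(ng, 5, 10)
    names(mu) <- gene_ids
    if (has_driver) mu[truth$driver_gene] <- 8
    tum_ids <- sprintf("t%03d", seq_len(n_tumor))
    nor_ids <- sprintf("n%03d", seq_len(n_normal))
    expr <- matrix(stats::rnorm((n_tumor + n_normal) * ng, mu, 1),
                   nrow = ng,
                   dimnames = list(gene_ids, c(tum_ids, nor_ids)))
    if (has_driver) {
      expr[truth$driver_gene, tum_ids] <-
        expr[truth$driver_gene, tum_ids] + truth$expr_shift
    }
    cn <- matrix(2 + stats::rnorm((n_tumor + n_normal) * ng, 0, 0.15),
                 nrow = ng,
                 dimnames = list(gene_ids, c(tum_ids, nor_ids)))
    if (has_driver && truth$cn_loss_fraction > 0) {
      lost <- stats::runif(n_tumor) < truth$cn_loss_fraction
      cn[truth$driver_gene, tum_ids[lost]] <-
        1 + stats::rnorm(sum(lost), 0, 0.15)
    }
    rate0 <- log(2) / base_median_survival
    rate <- rep(rate0, n_tumor)
    if (has_driver) {
      dx <- expr[truth$driver_gene, tum_ids]
      rate[dx < stats::median(dx)] <- rate0 * truth$hazard_ratio
    }
    death <- stats::rexp(n_tumor, rate)
    cens <- stats::runif(n_tumor, 0, horizon)
    survival <- tibble::tibble(
      sample = tum_ids,
      time = pmin(death, cens),
      event = as.numeric(death <= cens)
    )
    samples <- tibble::tibble(
      sample = c(tum_ids, nor_ids),
      group = c(rep("tumor", n_tumor), rep("normal", n_normal))
    )
    cohort_table(expr, samples, cn = cn, survival = survival)
  })
  attr(out, "truth") <- truth
  out
}
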