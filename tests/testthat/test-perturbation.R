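test_that("MOMA is the identity when the reference stays feasible", {
  toy <- make_toy_model(seed = 1)
  v_ref <- fba(toy$model)
  res <- moma(toy$model, v_ref)
  expect_equal(res$distance, 0, tolerance = 1e-6)
  expect_equal(res$flux$v, v_ref$v, tolerance = 1e-5)
  # knocking out a gene whose reaction already carries no flux
  res0 <- moma(toy$model, v_ref, knockout = "gZRO")
  expect_equal(res0$distance, 0, tolerance = 1e-6)
  expect_equal(res0$flux$v, v_ref$v, tolerance = 1e-5)
})

test_that("MOMA distance on a severed chain equals the hand value", {
  m <- chain_model(cap = 10)
  v_ref <- fba(m)  # (-10, 10, 10)
  res <- moma(m, v_ref, knockout = "g1")
  expect_equal(unname(res$flux$v), c(0, 0, 0), tolerance = 1e-5)
  expect_equal(res$distance, 100 + 100 + 100, tolerance = 1e-3)
})

test_that("MOMA distinguishes infeasibility from large distances", {
  toy <- make_toy_model(seed = 1)  # OXID has an obligatory minimum flux
  v_ref <- fba(toy$model)
  expect_error(moma(toy$model, v_ref, knockout = "gGLYC1"),
               "infeasible")
})

test_that("MOMA distance is zero iff the reference is feasible", {
  m <- parallel_model()
  v_ref <- fba(m)  # P1 = P2 = 5
  tight <- tibble::tibble(id = "P1", lb = 0, ub = 3)
  res <- moma(m, v_ref, bounds = tight)
  expect_gt(res$distance, 1e-4)   # reference cut off => positive distance
  loose <- tibble::tibble(id = "P1", lb = 0, ub = 5)
  expect_equal(moma(m, v_ref, bounds = loose)$distance, 0,
               tolerance = 1e-6)
})

test_that("binomial validation reproduces closed forms", {
  expect_equal(binomial_validation(0, 5, 0.2, mode = "point"), 0.8^5)
  expect_equal(binomial_validation(13, 19, 0.2, mode = "point"),
               stats::dbinom(13, 19, 0.2))
  # the tail always dominates the point mass
  withr::with_seed(3, {
    for (i in 1:20) {
      n <- sample(5:30, 1); k <- sample(0:n, 1)
      p <- stats::runif(1, 0.05, 0.95)
      expect_gte(binomial_validation(k, n, p, "tail") + 1e-12,
                 binomial_validation(k, n, p, "point"))
    }
  })
  expect_error(binomial_validation(5, 3, 0.2), "successes")
  expect_error(binomial_validation(1, 3, 1.2), "rate")
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  universe <- paste0("r", 1:10)
  pw <- list(path = paste0("r", 1:4))
  # hits drawn entirely from the pathway: C(K,k)/C(N,k)
  res <- hypergeometric_enrichment(paste0("r", 1:3), pw, universe)
  expect_equal(res$p, choose(4, 3) / choose(10, 3))
  # exhaustive oracle over all k-subsets of a small universe
  hits <- c("r1", "r2", "r6")
  obs <- hypergeometric_enrichment(hits, pw, universe)$overlap
  all_subsets <- utils::combn(10, 3)
  frac <- mean(apply(all_subsets, 2, function(s)
    sum(s <= 4) >= obs))
  expect_equal(hypergeometric_enrichment(hits, pw, universe)$p, frac,
               tolerance = 1e-12)
})

test_that("knockdown beats overexpression on the precursor-drain fixture", {
  m <- drain_model()
  expr <- c(gC = 10, gX = 10)  # nothing below threshold
  cmp <- compare_kd_oe(m, expr, "gX", n = 100, seed = 5,
                       biomass_fraction = 0.5)
  expect_equal(sum(cmp$samples$arm == "KD"), 100)
  expect_equal(sum(cmp$samples$arm == "OE"), 100)
  kd_bm <- cmp$samples$biomass[cmp$samples$arm == "KD"]
  oe_bm <- cmp$samples$biomass[cmp$samples$arm == "OE"]
  expect_gt(stats::median(kd_bm), stats::median(oe_bm))
  p <- cmp$tests$p[cmp$tests$readout == "biomass" &
                     cmp$tests$direction == "KD>OE"]
  expect_lt(p, 0.05)
  expect_error(compare_kd_oe(m, expr, "nope", n = 5, seed = 1),
               "not in model")
})

test_that("a zero-flux gene yields indistinguishable KD and OE arms", {
  toy <- make_toy_model(seed = 1)
  expr <- stats::setNames(rep(10, length(toy$model$genes)),
                          toy$model$genes)
  cmp <- compare_kd_oe(toy$model, expr, "gZRO", n = 30, seed = 2,
                       biomass_fraction = 0.8)
  expect_true(all(cmp$tests$p > 0.05))
})

test_that("flux change sets are empty for an inert knockout and calibrated", {
  toy <- make_toy_model(seed = 1)
  expr <- stats::setNames(rep(10, length(toy$model$genes)),
                          toy$model$genes)
  fcs <- flux_change_sets(toy$model, expr, "gZRO", n = 40, seed = 3,
                          biomass_fraction = 0.8)
  expect_length(fcs$increased, 0)
  expect_length(fcs$decreased, 0)
  # per-direction call count within the binomial envelope at alpha
  n_rxn <- nrow(fcs$table)
  upper <- stats::qbinom(0.995, n_rxn, fcs$alpha)
  expect_lte(length(fcs$increased), upper)
  expect_lte(length(fcs$decreased), upper)
  expect_error(flux_change_sets(toy$model, expr, "gZRO", n = 1),
               "n >= 2")
})

test_that("a rerouting knockout populates directional sets and enrichment", {
  toy <- make_toy_model(seed = 1)
  expr <- stats::setNames(rep(10, length(toy$model$genes)),
                          toy$model$genes)
  ferm <- toy$truth$rf_reactions
  pathways <- list(fermentation = c(ferm, "EX_lac"),
                   respiration = c("OXID", "EX_o2"))
  fcs <- flux_change_sets(toy$model, expr, "gDRV", n = 40, seed = 4,
                          pathways = pathways, biomass_fraction = 0.8)
  expect_true(all(ferm %in% fcs$increased))
  expect_true("OXID" %in% fcs$decreased)
  expect_length(intersect(fcs$increased, fcs$decreased), 0)
  p_ferm <- fcs$enrichment$p[fcs$enrichment$pathway == "fermentation"]
  p_resp <- fcs$enrichment$p[fcs$enrichment$pathway == "respiration"]
  expect_lt(p_ferm, 0.05)
  expect_gt(p_resp, p_ferm)
})

# a model with four independent expression-gated modules plus a growth
# chain: each tumor stage shuts one more module down, so post-knockout
# states of later stages sit closer to the advanced-stage target
staged_model <- function() {
  mets <- tibble::tibble(id = c(paste0("n", 1:4), paste0("w", 1:4),
                                "s", "bio"))
  mod_ids <- paste0("MOD", 1:4)
  rxns <- tibble::tibble(
    id = c(paste0("EX_n", 1:4), mod_ids, paste0("EX_w", 1:4),
           "EX_s", "GROW", "BIOMASS"),
    lb = c(rep(-5, 4), rep(0, 4), rep(0, 4), -10, 0, 0),
    ub = c(rep(0, 4), rep(1000, 4), rep(1000, 4), 0, 1000, 1000),
    gpr = c(rep("", 4), paste0("gM", 1:4), rep("", 4), "", "gG", "")
  )
  S <- matrix(0, nrow(mets), nrow(rxns),
              dimnames = list(mets$id, rxns$id))
  for (i in 1:4) {
    S[paste0("n", i), paste0("EX_n", i)] <- -1
    S[paste0("n", i), paste0("MOD", i)] <- -1
    S[paste0("w", i), paste0("MOD", i)] <- 1
    S[paste0("w", i), paste0("EX_w", i)] <- -1
  }
  S["s", "EX_s"] <- -1; S["s", "GROW"] <- -1
  S["bio", "GROW"] <- 1; S["bio", "BIOMASS"] <- -1
  metabolic_model(mets, rxns, S, objective_id = "BIOMASS",
                  exchange_ids = c(paste0("EX_n", 1:4),
                                   paste0("EX_w", 1:4), "EX_s"))
}

test_that("stage-staggered module shutdown yields a monotone distance", {
  m <- staged_model()
  # stage s expresses modules s..3 (module i shuts down from stage i+1);
  # module 4 is the knocked-out driver's and stays expressed
  profile_for <- function(stage) {
    v <- c(gG = 10, gM4 = 8,
           gM1 = if (stage >= 2) 0.05 else 8,
           gM2 = if (stage >= 3) 0.05 else 8,
           gM3 = if (stage >= 4) 0.05 else 8)
    v[c("gG", paste0("gM", 1:4))]
  }
  stages <- rep(1:4, each = 3)
  expr <- withr::with_seed(17, {
    cols <- lapply(stages, function(s)
      pmax(profile_for(s) + stats::rnorm(5, 0, 0.02), 0.01))
    do.call(cbind, cols)
  })
  rownames(expr) <- c("gG", paste0("gM", 1:4))
  colnames(expr) <- sprintf("s%02d", seq_along(stages))
  meds_of <- function(engine) {
    sp <- stage_specific_moma(m, expr, stages, "gM4", engine = engine,
                              n = 60, seed = 9, gimme_threshold = 1)
    vapply(1:4, function(s)
      stats::median(sp$distances$distance[sp$distances$stage == s]),
      numeric(1))
  }
  meds <- meds_of("gimme")
  expect_true(all(diff(meds) < 0))
  # samples matching the stage-4 signature sit closest to the target
  expect_equal(which.min(meds), 4L)
  # the iMAT engine preserves the stage ordering of medians
  expect_identical(order(meds_of("imat")), order(meds))
  expect_error(stage_specific_moma(m, expr[, stages != 2],
                                   stages[stages != 2], "gM4"),
               "every stage")
})
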