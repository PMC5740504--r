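make_partition <- function() {
  # abstract 5-reaction universe: a,b must rise; c must fall; d,e stay
  reaction_partition(rf = c("a", "b"), rb = "c", rs = c("d", "e"))
}

test_that("transformation score reproduces hand-computed examples", {
  part <- make_partition()
  ref <- c(a = 0, b = 0, c = 0, d = 0, e = 0)
  # successes |dv| = {2, 3}; failure |dv| = {1}; stay |dv| = {1, 1}
  res <- c(a = 2, b = 3, c = 1, d = 1, e = 1)
  expect_equal(as.numeric(transformation_score(ref, res, part)),
               (5 - 1) / 2)
  # null perturbation scores zero
  expect_equal(as.numeric(transformation_score(ref, ref, part)), 0)
  # all required changes succeed with |dv| totalling 4 over stay 4
  part2 <- reaction_partition(rf = "a", rb = character(),
                              rs = c("d", "e"))
  res2 <- c(a = 4, b = 0, c = 0, d = 2, e = 2)
  expect_equal(as.numeric(transformation_score(ref, res2, part2)), 1)
})

test_that("transformation score derives success sets by the epsilon rule", {
  part <- make_partition()
  ref <- c(a = 0, b = 0, c = 0, d = 0, e = 0)
  res <- c(a = 0.05, b = 1, c = -1, d = 0.5, e = 0)
  ts <- transformation_score(ref, res, part, epsilon = 0.1)
  expect_setequal(attr(ts, "success"), c("b", "c"))
  expect_setequal(attr(ts, "unsuccess"), "a")
  expect_equal(as.numeric(ts), (2 - 0.05) / 0.5)
  expect_error(transformation_score(ref, res[-1], part), "length")
})

test_that("swapping required directions negates the numerator", {
  part <- reaction_partition(rf = c("a", "b"), rb = "c",
                             rs = c("d", "e"))
  flipped <- reaction_partition(rf = "c", rb = c("a", "b"),
                                rs = c("d", "e"))
  ref <- c(a = 0, b = 0, c = 0, d = 0, e = 0)
  res <- c(a = 2, b = 1, c = -3, d = 1, e = 2)  # all |dv| >= epsilon
  den <- sum(abs(res[c("d", "e")]))
  num1 <- as.numeric(transformation_score(ref, res, part)) * den
  num2 <- as.numeric(transformation_score(ref, res, flipped)) * den
  expect_equal(num1, -num2)
})

test_that("zero-change reactions do not move the score", {
  part <- reaction_partition(rf = c("a", "b"), rb = "c",
                             rs = c("d", "e"))
  bigger <- reaction_partition(rf = c("a", "b", "x"), rb = c("c", "y"),
                               rs = c("d", "e", "z"))
  ref <- c(a = 0, b = 0, c = 0, d = 0, e = 0, x = 1, y = 1, z = 1)
  res <- c(a = 2, b = 1, c = -3, d = 1, e = 2, x = 1, y = 1, z = 1)
  expect_equal(as.numeric(transformation_score(ref, res, part)),
               as.numeric(transformation_score(ref, res, bigger)))
})

test_that("reaction partitioning propagates replicate gene calls", {
  toy <- make_toy_model(seed = 1)
  m <- toy$model
  base <- stats::setNames(rep(5, length(m$genes)), m$genes)
  withr::with_seed(11, {
    src <- lapply(1:6, function(i) base + stats::rnorm(length(base), 0, 0.1))
    tgt <- lapply(1:6, function(i) {
      x <- base + stats::rnorm(length(base), 0, 0.1)
      x["gDRV"] <- x["gDRV"] - 4       # strongly down
      x["gFA1"] <- x["gFA1"] + 4       # isozyme up...
      x["gFB1"] <- x["gFB1"] - 4       # ...its partner down: conflict
      x
    })
    part <- partition_reactions(src, tgt, m)
    expect_true("OXID" %in% part$rb)
    expect_true("FERM1" %in% part$rs)   # conflicting calls stay
    # identical source and target: everything stays
    part0 <- partition_reactions(src, src, m)
    expect_length(part0$rf, 0)
    expect_length(part0$rb, 0)
    expect_setequal(part0$rs, m$reactions$id)
  })
})

test_that("single-pair partitioning falls back to fold-change calls", {
  toy <- make_toy_model(seed = 1)
  m <- toy$model
  src <- stats::setNames(rep(4, length(m$genes)), m$genes)
  tgt <- src
  tgt["gFA2"] <- 20    # > 2-fold up
  tgt["gDRV"] <- 0.5   # > 2-fold down
  part <- partition_reactions(src, tgt, m)
  expect_true("FERM2" %in% part$rf)
  expect_true("OXID" %in% part$rb)
  expect_error(
    partition_reactions(c(zz = 1), c(zz = 2), m), "no genes")
})

test_that("the control solve attains the reference state and scores zero", {
  toy <- make_toy_model(seed = 1)
  m <- toy$model
  pair <- generate_paired_expression(m, toy$truth, n_pairs = 1,
                                     seed = 3)[[1]]
  part <- partition_reactions(pair$source, pair$target, m)
  v_ref <- fba(m)
  res <- solve_mta(m, v_ref, part, "control")
  expect_equal(res$ts, 0)
  expect_equal(res$v_res$v, v_ref$v, tolerance = 1e-4)
  expect_equal(res$status, "optimal")
})

test_that("an inert knockout leaves the reference state untouched", {
  toy <- make_toy_model(seed = 1)
  m <- toy$model
  pair <- generate_paired_expression(m, toy$truth, n_pairs = 1,
                                     seed = 3)[[1]]
  part <- partition_reactions(pair$source, pair$target, m)
  v_ref <- fba(m)
  res <- solve_mta(m, v_ref, part, "gZRO")
  expect_equal(res$ts, 0)
  expect_equal(res$v_res$v, v_ref$v, tolerance = 1e-4)
})

test_that("the driver knockout achieves every required change", {
  toy <- make_toy_model(seed = 1)
  m <- toy$model
  pair <- generate_paired_expression(m, toy$truth, n_pairs = 1,
                                     seed = 3)[[1]]
  part <- partition_reactions(pair$source, pair$target, m)
  v_ref <- fba(m)
  res <- solve_mta(m, v_ref, part, "gDRV")
  expect_setequal(res$success, c(part$rf, part$rb))
  expect_gt(res$ts, 0)
})

test_that("solve_mta matches the exhaustive MIQP oracle", {
  for (seed in c(1, 2, 3)) {
    toy <- make_toy_model(seed = seed)
    m <- toy$model
    pair <- generate_paired_expression(m, toy$truth, n_pairs = 1,
                                       seed = seed + 10)[[1]]
    part <- partition_reactions(pair$source, pair$target, m)
    v_ref <- fba(m)
    for (cand in c("gDRV", "gGLYC1", "gAUX1", "control")) {
      got <- solve_mta(m, v_ref, part, cand)
      oracle <- brute_force_mta(m, v_ref, part, cand)
      if (got$status == "infeasible") {
        expect_true(is.na(oracle$success_count),
                    label = paste(seed, cand))
      } else {
        expect_equal(got$miqp_success_count, oracle$success_count,
                     label = paste(seed, cand))
        expect_equal(got$objective, oracle$objective, tolerance = 1e-4,
                     label = paste(seed, cand))
      }
    }
  }
})

test_that("rankings are sorted, tie-broken lexicographically, and marked", {
  toy <- make_toy_model(seed = 1)
  m <- toy$model
  pair <- generate_paired_expression(m, toy$truth, n_pairs = 1,
                                     seed = 3)[[1]]
  part <- partition_reactions(pair$source, pair$target, m)
  v_ref <- fba(m)
  rk <- rank_candidates(m, v_ref, part,
                        candidates = c("gZRO", "gAUX1", "gDRV"))
  expect_equal(rk$candidate[1], "gDRV")
  expect_true(any(rk$is_control))
  # gAUX1 and gZRO tie at 0 with the control; lexicographic order
  tied <- rk$candidate[rk$ts == 0]
  expect_identical(tied, sort(tied))
  expect_true(all(diff(rk$ts) <= 1e-12))
  expect_error(rank_candidates(m, v_ref, part, character()),
               "no candidate")
  expect_error(rank_candidates(m, v_ref, part, "missing_gene"),
               "not in model")
})

test_that("the implanted driver ranks in the top fifth of candidates", {
  toy <- make_toy_model(seed = 9)
  m <- toy$model
  pair <- generate_paired_expression(m, toy$truth, n_pairs = 1,
                                     seed = 99)[[1]]
  part <- partition_reactions(pair$source, pair$target, m)
  v_ref <- metdriver:::mta_reference_state(m, pair$source, "imat")
  rk <- rank_candidates(m, v_ref, part, candidates = model_genes(m))
  expect_lte(rk$percentile[rk$candidate == "gDRV"], 20)
})

test_that("the Euclidean score variant agrees on the driver's bucket", {
  # squared-difference analogue of the score: same top-20% verdict
  euclid_ts <- function(v_ref, v_res, part, epsilon = 0.1) {
    dv <- v_res$v - v_ref$v
    succ <- c(part$rf[dv[part$rf] >= epsilon],
              part$rb[dv[part$rb] <= -epsilon])
    uns <- setdiff(c(part$rf, part$rb), succ)
    den <- sum(dv[part$rs]^2)
    num <- sum(dv[succ]^2) - sum(dv[uns]^2)
    if (den < 1e-9) { if (abs(num) < 1e-9) 0 else sign(num) * 1e9 }
    else num / den
  }
  toy <- make_toy_model(seed = 9)
  m <- toy$model
  pair <- generate_paired_expression(m, toy$truth, n_pairs = 1,
                                     seed = 99)[[1]]
  part <- partition_reactions(pair$source, pair$target, m)
  v_ref <- fba(m)
  scores <- vapply(c(model_genes(m), "control"), function(g) {
    r <- solve_mta(m, v_ref, part, g)
    if (r$status == "infeasible") -1e9 else euclid_ts(v_ref, r$v_res, part)
  }, numeric(1))
  genes <- setdiff(names(scores), "control")
  pct <- 100 * rank(-scores[genes], ties.method = "min") / length(genes)
  expect_lte(pct[["gDRV"]], 20)
})
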