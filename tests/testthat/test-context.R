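test_that("GIMME gives zero penalty when all genes are expressed", {
  m <- chain_model()
  fd <- gimme(m, c(g1 = 10), threshold = 1, objective_fraction = 0.9)
  expect_equal(attr(fd, "penalty"), 0, tolerance = 1e-8)
  expect_gte(fd$objective_value + 1e-6, 0.9 * 10)
  validate_flux(m, fd)
})

test_that("GIMME trades penalised flux down to the objective floor", {
  # the only route uses the below-threshold reaction, so it carries
  # exactly the required fraction of the optimum
  m <- chain_model(cap = 10)
  fd <- gimme(m, c(g1 = 0.1), threshold = 1, objective_fraction = 0.8)
  expect_equal(unname(fd$v["R1"]), 8, tolerance = 1e-5)
  expect_equal(attr(fd, "penalty"), 0.9 * 8, tolerance = 1e-4)
})

test_that("GIMME refuses a context with no objective to protect", {
  m <- set_bounds(chain_model(), tibble::tibble(id = "EX_A", lb = 0,
                                                ub = 0))
  expect_error(gimme(m, c(g1 = 10), objective_fraction = 1),
               "no objective")
})

test_that("GIMME penalty is monotone non-increasing as the threshold drops", {
  toy <- make_toy_model(seed = 5)
  expr <- stats::setNames(seq(0.1, 2, length.out = 13), toy$model$genes)
  pens <- vapply(c(2, 1.5, 1, 0.5, 0.1), function(thr)
    attr(gimme(toy$model, expr, threshold = thr,
               objective_fraction = 0.5), "penalty"),
    numeric(1))
  expect_true(all(diff(pens) <= 1e-6))
})

test_that("iMAT activates high calls and matches exhaustive enumeration", {
  m <- chain_model()
  calls <- tibble::tibble(reaction = c("EX_A", "R1", "BIOMASS"),
                          call = c("moderate", "high", "moderate"))
  fd <- imat(m, calls, activation_eps = 1)
  expect_gte(abs(fd$v["R1"]), 1 - 1e-6)
  expect_equal(attr(fd, "agreement"), 1)
  # all-moderate: any feasible flux, agreement 0
  mod <- dplyr::mutate(calls, call = "moderate")
  expect_equal(attr(imat(m, mod), "agreement"), 0)
})

test_that("iMAT resolves high/low conflicts like the enumeration oracle", {
  # R1 and BIOMASS are stoichiometrically coupled: calling one high and
  # the other low is a conflict only one of which can be satisfied
  m <- chain_model()
  conflict <- tibble::tibble(reaction = c("EX_A", "R1", "BIOMASS"),
                             call = c("moderate", "high", "low"))
  fd <- imat(m, conflict, activation_eps = 1)
  expect_equal(attr(fd, "agreement"),
               brute_force_imat(m, conflict, activation_eps = 1))
  # richer model, mixed calls
  toy <- make_toy_model(seed = 6)
  calls <- tibble::tibble(
    reaction = c("GLYC", "OXID", "FERM1", "FERM2", "RESP"),
    call = c("high", "high", "low", "low", "high"))
  fd2 <- imat(toy$model, calls, activation_eps = 1)
  expect_equal(attr(fd2, "agreement"),
               brute_force_imat(toy$model, calls, activation_eps = 1))
  validate_flux(toy$model, fd2)
})

test_that("relaxing a conflicted call to moderate keeps iMAT agreement", {
  m <- chain_model()
  conflict <- tibble::tibble(reaction = c("EX_A", "R1", "BIOMASS"),
                             call = c("moderate", "high", "low"))
  full <- attr(imat(m, conflict), "agreement")
  relaxed <- dplyr::mutate(conflict,
                           call = replace(call, reaction == "BIOMASS",
                                          "moderate"))
  expect_gte(attr(imat(m, relaxed), "agreement"), full)
})

test_that("flux sampling is seeded, feasible and inside FVA ranges", {
  toy <- make_toy_model(seed = 1)
  s1 <- sample_flux_space(toy$model, n = 25, seed = 42)
  s2 <- sample_flux_space(toy$model, n = 25, seed = 42)
  expect_identical(lapply(s1, function(x) x$v),
                   lapply(s2, function(x) x$v))
  expect_length(s1, 25)
  # every draw already passed validate_flux; check FVA envelope too
  r <- fva(toy$model, objective_fraction = 0)
  mat <- do.call(rbind, lapply(s1, function(x) x$v))
  expect_true(all(sweep(mat, 2, r$max + 1e-5) <= 0))
  expect_true(all(sweep(mat, 2, r$min - 1e-5) >= 0))
})

test_that("sampler block means stabilise as the block length grows", {
  toy <- make_toy_model(seed = 2)
  s <- sample_flux_space(toy$model, n = 1000, seed = 7)
  x <- vapply(s, function(v) unname(v$v["RESP"]), numeric(1))
  block_sd <- function(width) {
    means <- vapply(seq(1, length(x) - width + 1, by = width),
                    function(i) mean(x[i:(i + width - 1)]), numeric(1))
    stats::sd(means)
  }
  expect_lt(block_sd(200), block_sd(25))
})

test_that("sampling an infeasible region errors", {
  m <- set_bounds(chain_model(),
                  tibble::tibble(id = c("EX_A", "BIOMASS"),
                                 lb = c(0, 5), ub = c(0, 10)))
  expect_error(sample_flux_space(m, n = 5, seed = 1), "infeasible")
})
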