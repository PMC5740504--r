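test_that("identical group matrices yield empty screens", {
  co <- toy_screen_cohort(seed = 1)
  # overwrite: tumors are literal copies of normals
  normals <- co$expr[, co$samples$sample[co$samples$group == "normal"]]
  idx <- co$samples$group == "tumor"
  co$expr[, co$samples$sample[idx][1:30]] <- normals[, 1:30]
  expect_equal(nrow(diff_expr_screen(co, alpha = 0.001)), 0)
  co$cn[, co$samples$sample[idx][1:30]] <-
    co$cn[, co$samples$sample[!idx]][, 1:30]
  expect_equal(nrow(cn_screen(co, q_threshold = 0.25)), 0)
  # no Q-value can be below zero
  expect_equal(nrow(cn_screen(toy_screen_cohort(seed = 2),
                              q_threshold = 0)), 0)
})

test_that("a strongly down-shifted gene is always discovered", {
  for (seed in 1:3) {
    co <- toy_screen_cohort(seed = seed, shift = -3)
    hits <- diff_expr_screen(co, alpha = 0.001)
    expect_true("driver" %in% hits$gene, label = paste("seed", seed))
  }
})

test_that("an implanted single-copy loss is retained at Q < 0.25", {
  truth <- synthetic_truth(driver_gene = "driver", expr_shift = 0,
                           cn_loss_fraction = 0.6, hazard_ratio = 1)
  for (seed in 1:3) {
    co <- generate_cohort(truth, n_tumor = 40, n_normal = 30,
                          seed = seed,
                          gene_ids = c("driver",
                                       sprintf("g%02d", 1:50)))
    hits <- cn_screen(co, q_threshold = 0.25)
    expect_true("driver" %in% hits$gene, label = paste("seed", seed))
  }
})

hand_cohort <- function(expr_vals, times, events) {
  n <- length(times)
  ids <- sprintf("s%02d", seq_len(n))
  expr <- matrix(rep(expr_vals, each = 1), nrow = 1,
                 dimnames = list("g", ids))
  cohort_table(expr,
               samples = tibble::tibble(sample = ids, group = "tumor"),
               survival = tibble::tibble(sample = ids, time = times,
                                         event = events))
}

test_that("KM dAUC reproduces the hand-integrated two-group example", {
  # low bin: all events at t=1; high bin: event-free through t=2
  co <- hand_cohort(expr_vals = c(1, 1, 10, 10),
                    times = c(1, 1, 2, 2),
                    events = c(1, 1, 0, 0))
  res <- km_delta_auc(co, "g", split = "median", horizon = 2)
  expect_equal(res$delta_auc, (1 * 1 + 0 * 1) - 2)
  # the default horizon stops at the shorter curve
  res_min <- km_delta_auc(co, "g", split = "median")
  expect_equal(res_min$horizon, 1)
  expect_equal(res_min$delta_auc, 1 - 1)
})

test_that("KM dAUC is antisymmetric and zero under identical survival", {
  withr::with_seed(21, {
    n <- 40
    expr_vals <- stats::rnorm(n)
    times <- stats::rexp(n, 0.1 * ifelse(expr_vals < 0, 2, 1))
    events <- stats::rbinom(n, 1, 0.8)
    co <- hand_cohort(expr_vals, times, events)
    co_flip <- hand_cohort(-expr_vals, times, events)
    a <- km_delta_auc(co, "g")
    b <- km_delta_auc(co_flip, "g")
    h <- min(a$horizon, b$horizon)
    a2 <- km_delta_auc(co, "g", horizon = h)
    b2 <- km_delta_auc(co_flip, "g", horizon = h)
    expect_equal(a2$delta_auc, -b2$delta_auc, tolerance = 1e-9)
    # identical survival in both bins: zero difference
    same <- hand_cohort(c(1, 2, 9, 10), times = c(3, 5, 3, 5),
                        events = c(1, 1, 1, 1))
    expect_equal(km_delta_auc(same, "g")$delta_auc, 0)
  })
})

test_that("uncensored dAUC equals the truncated mean-survival difference", {
  co <- hand_cohort(expr_vals = c(1, 2, 3, 8, 9, 10),
                    times = c(2, 4, 6, 3, 7, 9),
                    events = rep(1, 6))
  h <- 5
  res <- km_delta_auc(co, "g", horizon = h)
  closed_form <- mean(pmin(c(2, 4, 6), h)) - mean(pmin(c(3, 7, 9), h))
  expect_equal(res$delta_auc, closed_form, tolerance = 1e-9)
})

test_that("degenerate splits are reported as errors", {
  co <- hand_cohort(rep(5, 4), times = 1:4, events = rep(1, 4))
  expect_error(km_delta_auc(co, "g"), "degenerate")
  expect_error(km_delta_auc(co, "absent"), "not in expression")
})

test_that("quantile normalization matches its defining properties", {
  withr::with_seed(31, {
    mat <- matrix(stats::rexp(200, 0.2), nrow = 20,
                  dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    ref <- sort(stats::rnorm(20, 10))
    qn <- quantile_normalize(mat, ref)
    # every column carries exactly the reference distribution
    for (j in 1:10) {
      expect_equal(sort(unname(qn[, j])), sort(ref), tolerance = 1e-12)
      expect_equal(stats::cor(qn[, j], mat[, j], method = "spearman"), 1)
    }
    # idempotence and the constant-reference degenerate case
    expect_equal(quantile_normalize(qn, ref), qn, tolerance = 1e-12)
    expect_true(all(quantile_normalize(mat, rep(3, 20)) == 3))
    expect_error(quantile_normalize(mat, 1:5), "length")
  })
})

test_that("marker correlations recover self, reversed and noisy signals", {
  withr::with_seed(41, {
    n <- 200
    x <- stats::rnorm(n)
    y <- 0.5 * x + sqrt(1 - 0.25) * stats::rnorm(n)  # rho = 0.5
    cn <- rbind(a = x, b = rev(sort(x))[rank(x)], c = y,
                const = rep(2, n))
    rownames(cn) <- c("a", "b", "c", "const")
    colnames(cn) <- sprintf("s%03d", 1:n)
    expr <- cn
    co <- cohort_table(expr,
                       samples = tibble::tibble(sample = colnames(cn),
                                                group = "tumor"),
                       cn = cn)
    expect_equal(marker_correlation(co, "a", "a")$rho, 1)
    expect_equal(marker_correlation(co, "a", "b")$rho, -1)
    est <- marker_correlation(co, "a", "c")
    expect_lt(abs(est$rho - 0.5), 0.15)
    expect_lt(est$p, 0.001)
    expect_error(marker_correlation(co, "a", "const"), "constant")
  })
})

test_that("the three screens compose as a strict funnel", {
  truth <- synthetic_truth(driver_gene = "driver")
  co <- generate_cohort(truth, n_tumor = 60, n_normal = 30, seed = 8,
                        gene_ids = c("driver", sprintf("g%02d", 1:40)))
  de <- diff_expr_screen(co, alpha = 0.05)   # loose level to fill stages
  cn <- cn_screen(co, q_threshold = 0.5, genes = de$gene)
  expect_true(all(cn$gene %in% de$gene))
  km <- vapply(cn$gene, function(g)
    km_delta_auc(co, g)$delta_auc, numeric(1))
  survivors <- cn$gene[km < 0]
  expect_true(all(survivors %in% cn$gene))
  expect_true("driver" %in% survivors)
})
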