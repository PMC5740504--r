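# Fixtures and independent oracles, all built in code.

# linear chain: uptake (capacity 10) -> A -> B -> biomass
chain_model <- function(cap = 10) {
  mets <- tibble::tibble(id = c("A", "B"))
  rxns <- tibble::tibble(
    id = c("EX_A", "R1", "BIOMASS"),
    lb = c(-cap, 0, 0), ub = c(0, 1000, 1000),
    gpr = c("", "g1", "")
  )
  S <- matrix(c(-1, -1, 0,
                0, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(mets$id, rxns$id))
  metabolic_model(mets, rxns, S, objective_id = "BIOMASS",
                  exchange_ids = "EX_A")
}

# two parallel capacity-6 paths sharing a demand of 10
parallel_model <- function() {
  mets <- tibble::tibble(id = c("A", "B"))
  rxns <- tibble::tibble(
    id = c("EX_A", "P1", "P2", "BIOMASS"),
    lb = c(-10, 0, 0, 0), ub = c(0, 6, 6, 1000),
    gpr = c("", "gp1", "gp2", "")
  )
  S <- matrix(c(-1, -1, -1, 0,
                0, 1, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(mets$id, rxns$id))
  metabolic_model(mets, rxns, S, objective_id = "BIOMASS",
                  exchange_ids = "EX_A")
}

# precursor-drain fixture: gene gX wastes the biomass precursor
drain_model <- function() {
  mets <- tibble::tibble(id = c("A", "B"))
  rxns <- tibble::tibble(
    id = c("EX_A", "CONV", "DRAIN", "BIOMASS"),
    lb = c(-10, 0, 0, 0), ub = c(0, 1000, 5, 1000),
    gpr = c("", "gC", "gX", "")
  )
  S <- matrix(c(-1, -1, 0, 0,
                0, 1, -1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(mets$id, rxns$id))
  metabolic_model(mets, rxns, S, objective_id = "BIOMASS",
                  exchange_ids = "EX_A",
                  readouts = c(biomass = "BIOMASS", glucose = "EX_A",
                               lactate = "DRAIN", oxygen = "EX_A"))
}

# random small model whose FBA optimum a vertex oracle can certify
random_small_model <- function(seed, m = 2, n_extra = 3) {
  withr::with_seed(seed, {
    n <- m + n_extra
    repeat {
      S <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
      lb <- ifelse(stats::runif(n) < 0.4, -10, 0)
      ub <- rep(10, n)
      if (any(S[, n] != 0)) break
    }
    mets <- tibble::tibble(id = paste0("m", seq_len(m)))
    rxns <- tibble::tibble(id = paste0("r", seq_len(n)),
                           lb = lb, ub = ub, gpr = "")
    dimnames(S) <- list(mets$id, rxns$id)
    metabolic_model(mets, rxns, S, objective_id = rxns$id[n])
  })
}

# ORACLE: FBA optimum by enumerating basic feasible solutions (vertices
# of {S v = 0, lb <= v <= ub}); returns -Inf when infeasible
brute_force_fba <- function(model, objective_id = model$objective_id) {
  S <- as.matrix(model$S)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  cvec <- numeric(ncol(S))
  cvec[match(objective_id, model$reactions$id)] <- 1
  n <- ncol(S); m <- nrow(S)
  best <- -Inf
  combs <- utils::combn(n, n - m)
  for (j in seq_len(ncol(combs))) {
    fix <- combs[, j]
    free <- setdiff(seq_len(n), fix)
    Sf <- S[, free, drop = FALSE]
    if (abs(det(Sf)) < 1e-10) next
    grid <- expand.grid(rep(list(c(1, 2)), length(fix)))
    for (g in seq_len(nrow(grid))) {
      xv <- numeric(n)
      xv[fix] <- ifelse(grid[g, ] == 1, lb[fix], ub[fix])
      rhs <- -S[, fix, drop = FALSE] %*% xv[fix]
      xv[free] <- solve(Sf, rhs)
      if (all(xv >= lb - 1e-8) && all(xv <= ub + 1e-8)) {
        best <- max(best, sum(cvec * xv))
      }
    }
  }
  best
}

# ORACLE: iMAT agreement by exhaustive enumeration of activation
# patterns (high: forward / backward / unmet, low: off / unmet)
brute_force_imat <- function(model, calls, activation_eps = 1) {
  called <- calls[calls$call %in% c("high", "low"), ]
  idx <- match(called$reaction, model$reactions$id)
  p <- list(Aeq = as.matrix(model$S),
            beq = rep(0, nrow(model$metabolites)))
  feasible <- function(lb, ub) {
    !is.null(metdriver:::qp_project((lb + ub) / 2, p$Aeq, p$beq, lb, ub))
  }
  options_for <- function(kind) {
    if (kind == "high") c("fwd", "bwd", "none") else c("off", "none")
  }
  grids <- expand.grid(lapply(called$call, options_for),
                       stringsAsFactors = FALSE)
  best <- 0L
  for (g in seq_len(nrow(grids))) {
    lb <- model$reactions$lb; ub <- model$reactions$ub
    score <- 0L
    ok <- TRUE
    for (i in seq_along(idx)) {
      r <- idx[i]
      choice <- grids[g, i]
      if (choice == "fwd") {
        lb[r] <- max(lb[r], activation_eps); score <- score + 1L
      } else if (choice == "bwd") {
        ub[r] <- min(ub[r], -activation_eps); score <- score + 1L
      } else if (choice == "off") {
        lb[r] <- 0; ub[r] <- 0; score <- score + 1L
      }
      if (lb[r] > ub[r]) { ok <- FALSE; break }
    }
    if (ok && score > best && feasible(lb, ub)) best <- score
  }
  best
}

# ORACLE: MTA optimum by exhaustive enumeration over all binary success
# patterns, each checked by a direct quadprog call
brute_force_mta <- function(model, v_ref, partition, candidate,
                            params = mta_params()) {
  vr <- if (inherits(v_ref, "flux_distribution")) v_ref$v else v_ref
  ko <- if (identical(candidate, "control")) model
        else apply_knockout(model, candidate)
  Aeq <- as.matrix(ko$S)
  beq <- rep(0, nrow(ko$metabolites))
  lb <- ko$reactions$lb; ub <- ko$reactions$ub
  n <- length(lb)
  rs_idx <- match(partition$rs, model$reactions$id)
  w <- rep(1e-6, n); w[rs_idx] <- 1
  cand <- c(partition$rf, partition$rb)
  dirs <- c(rep(1, length(partition$rf)), rep(-1, length(partition$rb)))
  ord <- order(cand); cand <- cand[ord]; dirs <- dirs[ord]
  ci <- match(cand, model$reactions$id)
  solve_node <- function(subset) {
    Amat <- rbind(Aeq, diag(n), -diag(n))
    bvec <- c(beq, lb, -ub)
    for (j in subset) {
      a <- numeric(n)
      if (dirs[j] > 0) { a[ci[j]] <- 1; b <- vr[ci[j]] + params$epsilon }
      else { a[ci[j]] <- -1; b <- -(vr[ci[j]] - params$epsilon) }
      Amat <- rbind(Amat, a); bvec <- c(bvec, b)
    }
    sol <- tryCatch(
      quadprog::solve.QP(diag(w, n), w * vr, t(Amat), bvec, meq = nrow(Aeq)),
      error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    sum((sol$solution[rs_idx] - vr[rs_idx])^2)
  }
  base <- solve_node(integer())
  if (is.null(base)) {
    return(list(objective = NA_real_, success_count = NA_integer_))
  }
  best_obj <- -Inf; best_k <- 0L
  nc <- length(cand)
  for (mask in 0:(2^nc - 1)) {
    subset <- which(bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0)
    d <- solve_node(subset)
    if (is.null(d)) next
    obj <- params$alpha_weight * length(subset) -
      (1 - params$alpha_weight) * d
    if (obj > best_obj + 1e-9 ||
        (obj > best_obj - 1e-9 && length(subset) > best_k)) {
      best_obj <- obj; best_k <- length(subset)
    }
  }
  list(objective = best_obj, success_count = best_k)
}

# small cohort used across screen tests
toy_screen_cohort <- function(seed = 1, n_tumor = 30, n_normal = 30,
                              shift = 0, n_genes = 50,
                              driver = "driver") {
  truth <- synthetic_truth(driver_gene = driver, expr_shift = shift,
                           cn_loss_fraction = 0, hazard_ratio = 1,
                           seed = seed)
  generate_cohort(truth, n_tumor = max(n_tumor, 10),
                  n_normal = max(n_normal, 10), seed = seed,
                  gene_ids = c(driver, sprintf("g%03d", seq_len(n_genes))))
}
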