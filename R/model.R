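# The constraint-based metabolic model container.
#
# A model is the classic quadruple (S, v_min, v_max, GPR): a stoichiometric
# matrix over m metabolites and n reactions, finite flux bounds, Boolean
# gene-reaction rules, one objective (biomass) reaction and a set of
# exchange reactions. Exchanges follow the standard COBRA convention:
# written as "metabolite ->", so negative flux is uptake and positive flux
# is secretion.

#' Construct a metabolic model
#'
#' @param metabolites tibble/data.frame with columns `id` and optionally
#'   `compartment`.
#' @param reactions tibble/data.frame with columns `id`, `lb`, `ub` and
#'   optionally `gpr` (Boolean rule string, `""` for none).
#' @param S stoichiometric matrix, m metabolites x n reactions (dense or
#'   sparse); rows/columns must follow the order of `metabolites$id` /
#'   `reactions$id` (dimnames, if present, are checked).
#' @param objective_id id of the objective (biomass) reaction.
#' @param exchange_ids character vector of exchange reaction ids.
#' @param readouts optional named character vector mapping read-out names
#'   (e.g. `biomass`, `glucose`, `lactate`, `oxygen`) to reaction ids; used
#'   by the phenotype simulations.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, S, objective_id,
                            exchange_ids = character(), readouts = NULL) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  S <- Matrix::Matrix(S, sparse = TRUE)
  dimnames(S) <- list(metabolites$id, reactions$id)
  gpr_trees <- lapply(reactions$gpr, parse_gpr)
  names(gpr_trees) <- reactions$id
  genes <- sort(unique(unlist(lapply(gpr_trees, gpr_genes))))
  model <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      S = S,
      gpr = gpr_trees,
      genes = genes,
      objective_id = objective_id,
      exchange_ids = exchange_ids,
      readouts = readouts
    ),
    class = "metabolic_model"
  )
  validate_model(model)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks matrix dimensions against the id lists, `lb <= ub` elementwise,
#' membership of the objective and exchange ids, and that every gene in a
#' GPR is in the model's gene list.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly usable in pipes; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  m <- nrow(model$metabolites); n <- nrow(model$reactions)
  if (!all(dim(model$S) == c(m, n))) {
    stop("stoichiometric matrix is ", nrow(model$S), "x", ncol(model$S),
         " but id lists declare ", m, "x", n, call. = FALSE)
  }
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicated metabolite ids", call. = FALSE)
  }
  if (anyDuplicated(model$reactions$id)) {
    stop("duplicated reaction ids", call. = FALSE)
  }
  if (!all(is.finite(model$reactions$lb)) ||
      !all(is.finite(model$reactions$ub))) {
    stop("flux bounds must be finite (cap unbounded reactions explicitly)",
         call. = FALSE)
  }
  bad <- model$reactions$lb > model$reactions$ub
  if (any(bad)) {
    stop("lb > ub for reaction(s): ",
         paste(model$reactions$id[bad], collapse = ", "), call. = FALSE)
  }
  if (!model$objective_id %in% model$reactions$id) {
    stop("objective reaction '", model$objective_id, "' not in model",
         call. = FALSE)
  }
  missing_ex <- setdiff(model$exchange_ids, model$reactions$id)
  if (length(missing_ex)) {
    stop("exchange id(s) not in model: ",
         paste(missing_ex, collapse = ", "), call. = FALSE)
  }
  used <- unique(unlist(lapply(model$gpr, gpr_genes)))
  if (!all(used %in% model$genes)) {
    stop("GPR references gene(s) outside the model gene list: ",
         paste(setdiff(used, model$genes), collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", length(x$genes), " genes\n",
      sep = "")
  cat("  objective: ", x$objective_id, "; exchanges: ",
      length(x$exchange_ids), "\n", sep = "")
  invisible(x)
}

#' Reactions of a model as a tibble
#' @param model a `metabolic_model`.
#' @return tibble with id, lb, ub, gpr and an `is_exchange` flag.
#' @export
model_reactions <- function(model) {
  dplyr::mutate(model$reactions,
                is_exchange = .data$id %in% model$exchange_ids)
}

#' Genes of a model
#' @param model a `metabolic_model`.
#' @return character vector of gene ids appearing in any GPR.
#' @export
model_genes <- function(model) model$genes

#' Gene-to-reaction incidence
#' @param model a `metabolic_model`.
#' @return tibble with columns `gene`, `reaction`.
#' @export
gene_reaction_map <- function(model) {
  purrr::map_dfr(model$reactions$id, function(r) {
    g <- gpr_genes(model$gpr[[r]])
    if (length(g) == 0) return(NULL)
    tibble::tibble(gene = g, reaction = r)
  })
}

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Simulate a gene knockout
#'
#' Every reaction whose GPR evaluates to FALSE with the given genes absent
#' has its bounds set to (0, 0); all other reactions are untouched. The
#' input model is not modified.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of gene ids to remove.
#' @return a new `metabolic_model` with the knockout applied.
#' @export
apply_knockout <- function(model, genes) {
  genes <- unique(genes)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  off <- vapply(model$reactions$id, function(r) {
    tree <- model$gpr[[r]]
    !is.null(tree) && !gpr_eval_bool(tree, genes)
  }, logical(1))
  model$reactions$lb[off] <- 0
  model$reactions$ub[off] <- 0
  model
}

#' Define a growth medium
#'
#' @param bounds named list or tibble mapping exchange reaction ids to
#'   `c(uptake, secretion)` bounds, with `uptake <= 0 <= secretion`
#'   (negative flux = uptake).
#' @param name medium label.
#' @return object of class `md_media`.
#' @export
media <- function(bounds, name = "custom") {
  if (is.data.frame(bounds)) {
    b <- purrr::map2(bounds$lb, bounds$ub, c)
    names(b) <- bounds$id
    bounds <- b
  }
  for (id in names(bounds)) {
    bb <- bounds[[id]]
    if (length(bb) != 2 || bb[1] > 0 || bb[2] < 0) {
      stop("media bounds for '", id, "' must satisfy uptake <= 0 <= secretion",
           call. = FALSE)
    }
  }
  structure(list(bounds = bounds, name = name), class = "md_media")
}

#' Apply a medium to a model
#'
#' Exchange reactions named by the medium get its bounds; every other
#' exchange is closed to uptake (lower bound 0) with secretion left open.
#'
#' @param model a `metabolic_model`.
#' @param med an `md_media` object (see [media()]).
#' @param secretion_cap upper bound used for "unbounded" secretion.
#' @return a new `metabolic_model`.
#' @export
set_media <- function(model, med, secretion_cap = 1000) {
  stopifnot(inherits(med, "md_media"))
  bad <- setdiff(names(med$bounds), model$exchange_ids)
  if (length(bad)) {
    stop("media names non-exchange reaction(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (id in model$exchange_ids) {
    i <- rxn_index(model, id)
    if (id %in% names(med$bounds)) {
      model$reactions$lb[i] <- med$bounds[[id]][1]
      model$reactions$ub[i] <- med$bounds[[id]][2]
    } else {
      model$reactions$lb[i] <- 0
      model$reactions$ub[i] <- secretion_cap
    }
  }
  model
}

#' Override selected reaction bounds
#' @param model a `metabolic_model`.
#' @param overrides tibble with columns `id`, `lb`, `ub`.
#' @return a new `metabolic_model`.
#' @export
set_bounds <- function(model, overrides) {
  idx <- rxn_index(model, overrides$id)
  model$reactions$lb[idx] <- overrides$lb
  model$reactions$ub[idx] <- overrides$ub
  validate_model(model)
  model
}
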