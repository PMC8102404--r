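# Core representation of a constraint-based metabolic model.
#
# A `metabolic_model` is a plain list with:
#   metabolites : data.frame(id, name, compartment, hmdb_id)
#   reactions   : data.frame(id, name, lower_bound, upper_bound, subsystem,
#                            gene_reaction_rule)
#   stoichiometry : dense numeric matrix, metabolites x reactions
#   objective   : list(reaction = <id>, direction = "max"|"min")
#   annotations : opaque per-element metadata preserved from the source file
#
# Sign convention for exchange reactions: positive flux = secretion (export),
# negative flux = uptake. This is stated in every text report the package
# writes.

#' Construct a metabolic model
#'
#' Builds and validates the package's constraint-based model container.
#'
#' @param metabolites data.frame with at least an `id` column; optional
#'   `name`, `compartment`, `hmdb_id`.
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`; optional `name`, `subsystem` (empty string when absent,
#'   never `NA`), `gene_reaction_rule`.
#' @param stoichiometry either a metabolites x reactions numeric matrix or a
#'   named list mapping reaction id -> named coefficient vector
#'   (metabolite id -> coefficient).
#' @param objective list with `reaction` (a reaction id) and `direction`
#'   (`"max"` or `"min"`); may be `NULL` for objective-free models.
#' @param annotations optional list of opaque metadata, preserved verbatim.
#' @param id model identifier string.
#'
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective = NULL, annotations = list(),
                            id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"id" %in% names(metabolites)) stop("metabolites need an 'id' column")
  if (!"id" %in% names(reactions)) stop("reactions need an 'id' column")
  for (col in c("name", "compartment", "hmdb_id")) {
    if (!col %in% names(metabolites)) metabolites[[col]] <- ""
  }
  for (col in c("name", "subsystem", "gene_reaction_rule")) {
    if (!col %in% names(reactions)) reactions[[col]] <- ""
  }
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  reactions$gene_reaction_rule[is.na(reactions$gene_reaction_rule)] <- ""
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")

  if (is.list(stoichiometry) && !is.matrix(stoichiometry)) {
    S <- matrix(0, nrow(metabolites), nrow(reactions),
                dimnames = list(metabolites$id, reactions$id))
    for (rid in names(stoichiometry)) {
      coefs <- stoichiometry[[rid]]
      if (!rid %in% reactions$id) {
        stop("stoichiometry given for undeclared reaction '", rid, "'")
      }
      bad <- setdiff(names(coefs), metabolites$id)
      if (length(bad)) {
        stop("validation error: reaction '", rid,
             "' references undeclared metabolite(s): ",
             paste(bad, collapse = ", "))
      }
      S[names(coefs), rid] <- as.numeric(coefs)
    }
    stoichiometry <- S
  } else {
    stoichiometry <- as.matrix(stoichiometry)
    if (is.null(dimnames(stoichiometry))) {
      dimnames(stoichiometry) <- list(metabolites$id, reactions$id)
    }
    if (!identical(rownames(stoichiometry), metabolites$id) ||
        !identical(colnames(stoichiometry), reactions$id)) {
      stop("stoichiometry dimnames must match metabolite and reaction ids")
    }
  }

  bad_bounds <- reactions$lower_bound > reactions$upper_bound
  if (any(bad_bounds)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(reactions$id[bad_bounds], collapse = ", "))
  }
  if (!is.null(objective)) {
    if (!objective$reaction %in% reactions$id) {
      stop("objective reaction '", objective$reaction, "' not in model")
    }
    if (is.null(objective$direction)) objective$direction <- "max"
    objective$direction <- match.arg(objective$direction, c("max", "min"))
  }

  structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, objective = objective,
         annotations = annotations),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions), "\n", sep = "")
  if (!is.null(x$objective)) {
    cat("  objective:   ", x$objective$direction, " ", x$objective$reaction,
        "\n", sep = "")
  }
  cat("  convention:  positive exchange flux = secretion, negative = uptake\n")
  invisible(x)
}

#' Summarise a metabolic model as a text report
#'
#' @param object a `metabolic_model`.
#' @param ... unused.
#' @return character vector of report lines (also printed).
#' @export
summary.metabolic_model <- function(object, ...) {
  subsys <- table(object$reactions$subsystem[object$reactions$subsystem != ""])
  lines <- c(
    sprintf("Model %s: %d metabolites, %d reactions", object$id,
            nrow(object$metabolites), nrow(object$reactions)),
    "Exchange sign convention: positive = secretion, negative = uptake",
    sprintf("Reversible reactions: %d",
            sum(object$reactions$lower_bound < 0 &
                  object$reactions$upper_bound > 0)),
    sprintf("Subsystems: %d", length(subsys))
  )
  if (length(subsys)) {
    top <- sort(subsys, decreasing = TRUE)
    top <- utils::head(top, 10)
    lines <- c(lines, paste0("  ", names(top), ": ", as.integer(top)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

n_reactions <- function(model) nrow(model$reactions)
n_metabolites <- function(model) nrow(model$metabolites)

reaction_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction(s): ", paste(id[is.na(i)], collapse = ", "))
  i
}

#' Identify exchange reactions
#'
#' An exchange reaction touches exactly one metabolite (single nonzero
#' stoichiometric entry), the usual boundary-reaction pattern.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  nz <- colSums(model$stoichiometry != 0)
  model$reactions$id[nz == 1]
}

#' Check a flux vector against model invariants
#'
#' @param model a `metabolic_model`.
#' @param v named or ordered numeric flux vector (length = #reactions).
#' @param eps_mass mass-balance tolerance on the infinity norm of `S v`.
#' @param eps_bound bound-violation tolerance.
#' @return `TRUE` invisibly, or stops with the violated invariant.
#' @export
check_flux_vector <- function(model, v, eps_mass = 1e-6, eps_bound = 1e-9) {
  v <- as.numeric(v)
  stopifnot(length(v) == n_reactions(model))
  resid <- max(abs(model$stoichiometry %*% v))
  if (resid > eps_mass) {
    stop("mass-balance violation: ||S v||_inf = ", format(resid))
  }
  lo <- v - model$reactions$lower_bound
  hi <- model$reactions$upper_bound - v
  if (min(lo, hi) < -eps_bound) {
    stop("bound violation of ", format(-min(lo, hi)))
  }
  invisible(TRUE)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the model objective subject to steady-state mass
#' balance `S v = 0` and the reaction bounds.
#'
#' @param model a `metabolic_model` with a non-`NULL` objective.
#' @param objective optional reaction id overriding the model objective.
#' @param direction optional `"max"`/`"min"` overriding the model objective.
#' @return list with `status` (`"optimal"` or `"infeasible"`),
#'   `objective_value` and `fluxes` (named vector; `NA` unless optimal).
#' @export
fba <- function(model, objective = NULL, direction = NULL) {
  obj_rxn <- objective %||% model$objective$reaction
  if (is.null(obj_rxn)) stop("model has no objective")
  dir <- direction %||% (model$objective$direction %||% "max")
  c_vec <- numeric(n_reactions(model))
  c_vec[reaction_index(model, obj_rxn)] <- 1
  res <- solve_lp(c_vec, model$stoichiometry,
                  numeric(n_metabolites(model)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  maximize = identical(dir, "max"))
  fluxes <- res$solution
  names(fluxes) <- model$reactions$id
  list(status = res$status, objective_value = res$objective, fluxes = fluxes)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective stays at or above `fraction_of_optimum` times its optimum.
#'
#' @param model a `metabolic_model`.
#' @param fraction_of_optimum number in `[0, 1]`; 0 drops the optimality
#'   constraint entirely.
#' @param reactions optional subset of reaction ids.
#' @return list with `status` and, when optimal, a data.frame
#'   (`reaction`, `min`, `max`).
#' @export
fva <- function(model, fraction_of_optimum = 1, reactions = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  work <- model
  if (fraction_of_optimum > 0 && !is.null(model$objective)) {
    base <- fba(model)
    if (base$status != "optimal") {
      return(list(status = base$status, ranges = NULL))
    }
    i <- reaction_index(model, model$objective$reaction)
    target <- fraction_of_optimum * base$objective_value
    if (identical(model$objective$direction %||% "max", "max")) {
      work$reactions$lower_bound[i] <- max(work$reactions$lower_bound[i],
                                           min(target, base$objective_value))
    } else {
      work$reactions$upper_bound[i] <- min(work$reactions$upper_bound[i], target)
    }
  } else {
    # still verify feasibility once
    probe <- solve_lp(numeric(n_reactions(model)), model$stoichiometry,
                      numeric(n_metabolites(model)),
                      model$reactions$lower_bound,
                      model$reactions$upper_bound)
    if (probe$status != "optimal") {
      return(list(status = "infeasible", ranges = NULL))
    }
  }
  ids <- reactions %||% model$reactions$id
  idx <- reaction_index(model, ids)
  mins <- maxs <- numeric(length(idx))
  Svec <- numeric(n_metabolites(model))
  for (k in seq_along(idx)) {
    c_vec <- numeric(n_reactions(model))
    c_vec[idx[k]] <- 1
    lo <- solve_lp(c_vec, work$stoichiometry, Svec,
                   work$reactions$lower_bound, work$reactions$upper_bound,
                   maximize = FALSE)
    hi <- solve_lp(c_vec, work$stoichiometry, Svec,
                   work$reactions$lower_bound, work$reactions$upper_bound,
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      return(list(status = "infeasible", ranges = NULL))
    }
    mins[k] <- lo$objective
    maxs[k] <- hi$objective
  }
  list(status = "optimal",
       ranges = data.frame(reaction = ids, min = mins, max = maxs,
                           stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
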