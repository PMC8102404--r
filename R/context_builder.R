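# Condition-specific model construction.
#
# Expression data are mapped onto reactions through gene-reaction rules
# (AND = min, OR = max), and reactions whose activity score falls below a
# threshold have their bounds softly scaled (a GIMME-like LP-only scheme,
# chosen over MILP extraction for determinism at desk scale). Metabolomics
# enter as directional constraints on exchange reactions. Knockouts close a
# reaction directly or re-evaluate every rule with the gene forced to zero.

#' Parse a gene-reaction rule
#'
#' Grammar: identifiers combined with `and` / `or` (case-insensitive) and
#' parentheses. Returns an AST: either a gene id (character scalar) or
#' `list(op = "and"|"or", args = list(...))`.
#'
#' @param rule rule string; empty string gives `NULL`.
#' @return parsed AST or `NULL` for empty rules.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || !nzchar(trimws(rule))) return(NULL)
  tokens <- gpr_tokenize(rule)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  ast <- gpr_parse_or(state, rule)
  if (state$pos <= length(state$tokens)) {
    stop("GPR parse error at token ", state$pos, " ('",
         state$tokens[state$pos], "') in rule: ", rule)
  }
  ast
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  tokens <- strsplit(trimws(rule), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

gpr_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_ else state$tokens[state$pos]
}

gpr_parse_or <- function(state, rule) {
  args <- list(gpr_parse_and(state, rule))
  while (!is.na(tok <- gpr_peek(state)) && tolower(tok) == "or") {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_and(state, rule)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(state, rule) {
  args <- list(gpr_parse_atom(state, rule))
  while (!is.na(tok <- gpr_peek(state)) && tolower(tok) == "and") {
    state$pos <- state$pos + 1L
    args <- c(args, list(gpr_parse_atom(state, rule)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(state, rule) {
  tok <- gpr_peek(state)
  if (is.na(tok)) stop("GPR parse error: unexpected end of rule: ", rule)
  if (tok == "(") {
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state, rule)
    if (!identical(gpr_peek(state), ")")) {
      stop("GPR parse error at token ", state$pos,
           ": expected ')' in rule: ", rule)
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("GPR parse error at token ", state$pos, " ('", tok,
         "') in rule: ", rule)
  }
  state$pos <- state$pos + 1L
  tok
}

#' Evaluate a gene-reaction rule against an expression profile
#'
#' AND nodes take the minimum of their children, OR nodes the maximum; genes
#' absent from the profile score `missing_value` (by default the profile
#' median, so unmeasured genes do not spuriously close reactions).
#'
#' @param rule rule string or pre-parsed AST from [parse_gpr()].
#' @param profile named numeric vector of nonnegative expression values.
#' @param missing_value score used for genes absent from `profile`; default
#'   `stats::median(profile)`.
#' @return numeric activity score; `NA` for empty rules.
#' @export
evaluate_gpr <- function(rule, profile, missing_value = NULL) {
  # accept either a raw rule string or a pre-parsed AST
  if (!is.list(rule) && is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) return(NA_real_)
  if (any(profile < 0, na.rm = TRUE)) stop("expression values must be nonnegative")
  if (is.null(missing_value)) missing_value <- stats::median(profile)
  eval_node <- function(node) {
    if (is.character(node)) {
      if (node %in% names(profile)) return(unname(profile[[node]]))
      return(missing_value)
    }
    vals <- vapply(node$args, eval_node, numeric(1))
    if (node$op == "and") min(vals) else max(vals)
  }
  eval_node(rule)
}

#' Reaction activity scores for a whole model
#'
#' @param model a `metabolic_model`.
#' @param profile named numeric expression vector.
#' @param missing_value see [evaluate_gpr()].
#' @return named numeric vector (reaction id -> score; `NA` for empty rules).
#' @export
reaction_activity <- function(model, profile, missing_value = NULL) {
  if (!length(intersect(names(profile), model_genes(model)))) {
    stop("expression profile shares no genes with the model")
  }
  if (is.null(missing_value)) missing_value <- stats::median(profile)
  scores <- vapply(model$reactions$gene_reaction_rule, function(rule) {
    ast <- parse_gpr(rule)
    if (is.null(ast)) NA_real_ else evaluate_gpr(ast, profile, missing_value)
  }, numeric(1), USE.NAMES = FALSE)
  stats::setNames(scores, model$reactions$id)
}

#' Genes referenced by a model's gene-reaction rules
#'
#' @param model a `metabolic_model`.
#' @return character vector of gene ids.
#' @export
model_genes <- function(model) {
  collect <- function(ast) {
    if (is.null(ast)) return(character(0))
    if (is.character(ast)) return(ast)
    unlist(lapply(ast$args, collect))
  }
  unique(unlist(lapply(model$reactions$gene_reaction_rule,
                       function(r) collect(parse_gpr(r)))))
}

#' Constrain a model with an expression profile
#'
#' Reactions whose activity score `a` falls below `threshold` have both
#' bounds multiplied by `max(floor, a / threshold)`; reactions at or above
#' threshold, and reactions without a rule, are untouched. The input model is
#' not modified.
#'
#' @param model a `metabolic_model`.
#' @param profile named numeric expression vector (nonnegative).
#' @param threshold expression-units cutoff; default the 25th percentile of
#'   the profile restricted to model genes.
#' @param floor minimum bound-scaling fraction in `[0, 1)`; default 0.
#' @param missing_value see [evaluate_gpr()].
#' @return a new constrained `metabolic_model`; the applied threshold and
#'   per-reaction scale factors are recorded under
#'   `annotations$expression_context`.
#' @export
apply_expression_constraints <- function(model, profile, threshold = NULL,
                                         floor = 0, missing_value = NULL) {
  stopifnot(floor >= 0, floor < 1)
  genes <- intersect(names(profile), model_genes(model))
  if (!length(genes)) stop("expression profile shares no genes with the model")
  if (is.null(threshold)) {
    threshold <- stats::quantile(profile[genes], 0.25, names = FALSE)
  }
  if (threshold <= 0) stop("threshold must be > 0")
  a <- reaction_activity(model, profile, missing_value)
  scale <- ifelse(is.na(a), 1, pmax(floor, pmin(a / threshold, 1)))
  # scaling always starts from the pristine bounds recorded at the first
  # application, so reapplying the same profile is idempotent
  base_lb <- model$annotations$expression_context$base_lower %||%
    model$reactions$lower_bound
  base_ub <- model$annotations$expression_context$base_upper %||%
    model$reactions$upper_bound
  out <- model
  out$reactions$lower_bound <- base_lb * scale
  out$reactions$upper_bound <- base_ub * scale
  out$annotations$expression_context <- list(
    threshold = threshold, floor = floor,
    base_lower = base_lb, base_upper = base_ub,
    scale = stats::setNames(scale, model$reactions$id))
  out
}

#' Read a two-column expression TSV (gene_id, value)
#'
#' @param path TSV path with a header line.
#' @return named numeric vector.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs two columns (gene_id, value)")
  v <- as.numeric(tab[[2]])
  if (any(v < 0, na.rm = TRUE)) stop("expression values must be nonnegative")
  stats::setNames(v, as.character(tab[[1]]))
}

#' Constrain exchange reactions with metabolomics-derived directions
#'
#' Sign convention: positive exchange flux = secretion, negative = uptake.
#' `secretion_min` raises the exchange lower bound to at least `magnitude`;
#' `uptake_min` lowers the upper bound to at most `-magnitude`; `blocked`
#' closes the exchange entirely.
#'
#' @param model a `metabolic_model`.
#' @param constraints data.frame with columns `metabolite_id`, `direction`
#'   (`secretion_min` / `uptake_min` / `blocked`) and `magnitude` (>= 0).
#' @return list with `model` (the constrained model) and `status`
#'   (`"feasible"` or `"infeasible"`); when infeasible, `offending` lists the
#'   constrained exchanges.
#' @export
apply_metabolite_constraints <- function(model, constraints) {
  constraints <- as.data.frame(constraints, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "direction", "magnitude") %in%
                  names(constraints)))
  if (any(constraints$magnitude < 0)) stop("constraint magnitudes must be >= 0")
  ex <- exchange_reactions(model)
  # map metabolite -> its exchange reaction
  ex_met <- vapply(ex, function(r) {
    col <- model$stoichiometry[, reaction_index(model, r)]
    rownames(model$stoichiometry)[which(col != 0)[1]]
  }, character(1))
  out <- model
  touched <- character(0)
  for (i in seq_len(nrow(constraints))) {
    met <- constraints$metabolite_id[i]
    hit <- ex[ex_met == met]
    if (!length(hit)) {
      stop("no exchange reaction for metabolite(s): ", met)
    }
    j <- reaction_index(model, hit[1])
    mag <- constraints$magnitude[i]
    dirn <- constraints$direction[i]
    # An exporting exchange has negative stoichiometry (met -> outside);
    # positive flux then removes the metabolite, i.e. secretion. Flip the
    # effective sign for exchanges written in the importing orientation.
    sgn <- if (model$stoichiometry[ex_met[hit[1]], j] < 0) 1 else -1
    if (dirn == "blocked") {
      out$reactions$lower_bound[j] <- 0
      out$reactions$upper_bound[j] <- 0
    } else if (dirn == "secretion_min") {
      if (sgn > 0) {
        out$reactions$lower_bound[j] <- max(out$reactions$lower_bound[j], mag)
      } else {
        out$reactions$upper_bound[j] <- min(out$reactions$upper_bound[j], -mag)
      }
    } else if (dirn == "uptake_min") {
      if (sgn > 0) {
        out$reactions$upper_bound[j] <- min(out$reactions$upper_bound[j], -mag)
      } else {
        out$reactions$lower_bound[j] <- max(out$reactions$lower_bound[j], mag)
      }
    } else {
      stop("unknown constraint direction: ", dirn)
    }
    touched <- c(touched, hit[1])
  }
  bad <- out$reactions$lower_bound > out$reactions$upper_bound
  status <- "feasible"
  if (any(bad)) {
    status <- "infeasible"
  } else {
    probe <- solve_lp(numeric(n_reactions(out)), out$stoichiometry,
                      numeric(n_metabolites(out)),
                      out$reactions$lower_bound, out$reactions$upper_bound)
    if (probe$status != "optimal") status <- "infeasible"
  }
  list(model = out, status = status,
       offending = if (status == "infeasible") unique(touched) else character(0))
}

#' Read a metabolite-constraint TSV (metabolite_id, direction, magnitude)
#'
#' @param path TSV path with a header line.
#' @return data.frame suitable for [apply_metabolite_constraints()].
#' @export
read_constraints_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "direction", "magnitude") %in% names(tab)))
  tab$magnitude <- as.numeric(tab$magnitude)
  tab
}

#' Knock out a reaction or a gene
#'
#' A reaction knockout sets that reaction's bounds to `(0, 0)`. A gene
#' knockout re-evaluates every gene-reaction rule under pure boolean
#' semantics (expressed = 1, knocked-out gene = 0) and closes reactions whose
#' rule evaluates to 0.
#'
#' @param model a `metabolic_model`.
#' @param target a reaction id or a gene id.
#' @return a new `metabolic_model`.
#' @export
knockout <- function(model, target) {
  out <- model
  if (target %in% model$reactions$id) {
    j <- reaction_index(model, target)
    out$reactions$lower_bound[j] <- 0
    out$reactions$upper_bound[j] <- 0
    return(out)
  }
  genes <- model_genes(model)
  if (!target %in% genes) {
    stop("unknown knockout target (neither reaction nor gene): ", target)
  }
  profile <- stats::setNames(rep(1, length(genes)), genes)
  profile[target] <- 0
  for (j in seq_len(n_reactions(model))) {
    ast <- parse_gpr(model$reactions$gene_reaction_rule[j])
    if (is.null(ast)) next
    if (evaluate_gpr(ast, profile, missing_value = 1) == 0) {
      out$reactions$lower_bound[j] <- 0
      out$reactions$upper_bound[j] <- 0
    }
  }
  out
}
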