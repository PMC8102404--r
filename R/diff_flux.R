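# Differential flux-state calling between two conditions.
#
# Per reaction, a one-way two-group ANOVA F statistic compares the sampled
# flux distributions of wildtype and knockout; a reaction is called altered
# when p < alpha AND the fold change of |mean| falls outside [fc_lo, fc_hi].
# No multiple-testing correction is applied by default (the raw-p +
# fold-change filter is the screening rule this mirrors); BH adjustment is
# available as an option.

#' Two-group ANOVA F test on flux samples
#'
#' `F = MS_between / MS_within` with `(1, n1 + n2 - 2)` degrees of freedom;
#' algebraically `F` equals the square of the pooled-variance t statistic.
#'
#' @param wt,ko numeric vectors of sampled flux values (>= 2 each).
#' @return list with `F`, `p` and `degenerate` (`TRUE` when both group
#'   variances are zero).
#' @export
reaction_ftest <- function(wt, ko) {
  n1 <- length(wt); n2 <- length(ko)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- mean(wt); m2 <- mean(ko)
  grand <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- sum((wt - m1)^2) + sum((ko - m2)^2)
  df2 <- n1 + n2 - 2
  if (ssw == 0) {
    if (isTRUE(all.equal(m1, m2))) {
      return(list(F = 0, p = 1, degenerate = TRUE))
    }
    return(list(F = Inf, p = 0, degenerate = TRUE))
  }
  Fstat <- (ssb / 1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Call altered reactions between two flux sample sets
#'
#' @param wt,ko `flux_sample_set` objects over the same reaction universe
#'   (typically l1-normalised; see [normalize_samples()]).
#' @param alpha significance threshold on the raw F-test p (default 0.001).
#' @param fc_hi,fc_lo fold-change thresholds (defaults 2 and 0.5): a
#'   reaction must change more than `fc_hi`-fold or less than `fc_lo`-fold.
#' @param eps_fc pseudocount added to |means| before the ratio (default 1e-9).
#' @param adjust_p also report BH-adjusted p values (reporting only; the
#'   altered call always uses the raw p, matching the screening rule).
#' @return a `diff_flux_result`: data.frame `table` with per-reaction
#'   `reaction`, `wt_mean`, `ko_mean`, `fold_change`, `sign_change`, `F`,
#'   `p` (optionally `p_adj`), `altered`; plus the thresholds used.
#' @export
call_altered_reactions <- function(wt, ko, alpha = 0.001, fc_hi = 2,
                                   fc_lo = 0.5, eps_fc = 1e-9,
                                   adjust_p = FALSE) {
  wt_m <- wt$samples; ko_m <- ko$samples
  if (!identical(colnames(wt_m), colnames(ko_m))) {
    only_wt <- setdiff(colnames(wt_m), colnames(ko_m))
    only_ko <- setdiff(colnames(ko_m), colnames(wt_m))
    if (length(only_wt) || length(only_ko)) {
      stop("sample sets cover different reactions; only in wt: {",
           paste(only_wt, collapse = ", "), "}; only in ko: {",
           paste(only_ko, collapse = ", "), "}")
    }
    ko_m <- ko_m[, colnames(wt_m), drop = FALSE]
  }
  n1 <- nrow(wt_m); n2 <- nrow(ko_m)
  m1 <- colMeans(wt_m); m2 <- colMeans(ko_m)
  grand <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- colSums(sweep(wt_m, 2, m1)^2) + colSums(sweep(ko_m, 2, m2)^2)
  df2 <- n1 + n2 - 2
  Fstat <- ifelse(ssw == 0, ifelse(abs(m1 - m2) < 1e-12, 0, Inf),
                  ssb / (ssw / df2))
  p <- ifelse(is.infinite(Fstat), 0,
              stats::pf(Fstat, 1, df2, lower.tail = FALSE))
  fc <- (abs(m2) + eps_fc) / (abs(m1) + eps_fc)
  sign_change <- (m1 * m2 < 0) & (abs(m1) > eps_fc) & (abs(m2) > eps_fc)
  altered <- (p < alpha) & (fc > fc_hi | fc < fc_lo)
  table <- data.frame(
    reaction = colnames(wt_m), wt_mean = m1, ko_mean = m2,
    fold_change = fc, sign_change = sign_change, F = Fstat, p = p,
    altered = altered, row.names = NULL, stringsAsFactors = FALSE)
  if (adjust_p) table$p_adj <- bh_adjust(table$p)
  structure(
    list(table = table, alpha = alpha, fc_hi = fc_hi, fc_lo = fc_lo,
         eps_fc = eps_fc, n_wt = n1, n_ko = n2),
    class = "diff_flux_result")
}

#' @export
print.diff_flux_result <- function(x, ...) {
  cat("<diff_flux_result> ", nrow(x$table), " reactions, ",
      sum(x$table$altered), " altered (p < ", x$alpha, ", FC > ", x$fc_hi,
      " or < ", x$fc_lo, ")\n", sep = "")
  invisible(x)
}

#' Default lipid subsystem keywords
#'
#' Case-insensitive substrings that mark a subsystem label as lipid-related,
#' mirroring how genome-scale reconstruction subsystems annotate lipid
#' chemistry.
#'
#' @return character vector.
#' @export
default_lipid_keywords <- function() {
  c("fatty acid", "bile acid", "eicosanoid", "prostaglandin", "sphingolipid",
    "glycerolipid", "glycerophospholipid", "cholesterol", "steroid",
    "carnitine", "squalene", "phosphatidylinositol")
}

#' Roll up altered reactions to subsystems and metabolites
#'
#' A metabolite is affected iff it has nonzero stoichiometry in at least one
#' altered reaction (`affected_mode = "all"`), or in at least one altered
#' exchange reaction (`affected_mode = "exchange"`). It is lipid-annotated
#' iff any of its altered reactions' subsystems matches the lipid keyword
#' list (case-insensitive substring).
#'
#' @param result a `diff_flux_result`.
#' @param model the `metabolic_model` the samples came from.
#' @param lipid_subsystems keyword vector; see [default_lipid_keywords()].
#' @param affected_mode `"all"` or `"exchange"`.
#' @return list with `subsystem_tally` (named integer vector),
#'   `affected_metabolites`, `lipid_metabolites` (character vectors) and
#'   `n_altered`.
#' @export
rollup <- function(result, model, lipid_subsystems = default_lipid_keywords(),
                   affected_mode = c("all", "exchange")) {
  affected_mode <- match.arg(affected_mode)
  if (!length(lipid_subsystems)) {
    warning("empty lipid keyword list; lipid subset will be empty")
  }
  altered_ids <- result$table$reaction[result$table$altered]
  idx <- match(altered_ids, model$reactions$id)
  if (anyNA(idx)) stop("altered reactions not found in model")
  subs <- model$reactions$subsystem[idx]
  subs[!nzchar(subs)] <- "(none)"
  tally <- table(subs)
  tally <- stats::setNames(as.integer(tally), names(tally))

  consider <- altered_ids
  if (affected_mode == "exchange") {
    consider <- intersect(altered_ids, exchange_reactions(model))
  }
  affected <- character(0)
  lipid <- character(0)
  is_lipid_sub <- function(s) {
    length(lipid_subsystems) > 0 &&
      any(vapply(lipid_subsystems,
                 function(k) grepl(k, s, ignore.case = TRUE, fixed = FALSE),
                 logical(1)))
  }
  for (rid in consider) {
    j <- match(rid, model$reactions$id)
    mets <- rownames(model$stoichiometry)[model$stoichiometry[, j] != 0]
    affected <- union(affected, mets)
    if (is_lipid_sub(model$reactions$subsystem[j])) {
      lipid <- union(lipid, mets)
    }
  }
  list(subsystem_tally = tally, affected_metabolites = affected,
       lipid_metabolites = lipid, n_altered = length(altered_ids))
}

#' Write differential-flux outputs as TSV (+ JSON rollup)
#'
#' @param result a `diff_flux_result`.
#' @param rollup_result output of [rollup()], optional.
#' @param path per-reaction TSV path; rollup files take `path` with
#'   `_rollup.tsv` / `_rollup.json` suffixes.
#' @export
write_diff_flux <- function(result, path, rollup_result = NULL) {
  con <- file(path, "w")
  writeLines(paste0("# differential flux states; sign convention: positive ",
                    "exchange flux = secretion, negative = uptake"), con)
  utils::write.table(result$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!is.null(rollup_result)) {
    base <- sub("\\.tsv$", "", path)
    utils::write.table(
      data.frame(subsystem = names(rollup_result$subsystem_tally),
                 altered_reactions = rollup_result$subsystem_tally),
      paste0(base, "_rollup.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(rollup_result, paste0(base, "_rollup.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
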