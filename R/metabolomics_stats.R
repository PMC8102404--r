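# Targeted-metabolomics differential statistics and subpathway enrichment.
#
# The container is a `metabolite_table`: an abundance matrix (samples x
# metabolites, nonnegative platform units, NA = missing), a sample -> group
# map, and per-metabolite annotations (superpathway, subpathway, optional
# HMDB id). Statistics are computed after group-minimum imputation, which is
# the order this pipeline commits to.

#' Construct a metabolite table
#'
#' @param abundance numeric matrix, samples x metabolites, with dimnames.
#' @param groups named character vector or factor mapping sample -> group
#'   label; must cover all rows of `abundance`.
#' @param annotations data.frame with columns `metabolite_id`,
#'   `superpathway`, `subpathway` and optional `hmdb_id`.
#' @return a `metabolite_table`.
#' @export
metabolite_table <- function(abundance, groups, annotations) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance matrix needs sample rownames and metabolite colnames")
  }
  groups <- stats::setNames(as.character(groups), names(groups))
  if (!all(rownames(abundance) %in% names(groups))) {
    stop("group labels must cover all samples")
  }
  groups <- groups[rownames(abundance)]
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!"metabolite_id" %in% names(annotations)) {
    stop("annotations need a 'metabolite_id' column")
  }
  if (!"hmdb_id" %in% names(annotations)) annotations$hmdb_id <- ""
  missing_ann <- setdiff(colnames(abundance), annotations$metabolite_id)
  if (length(missing_ann)) {
    stop("metabolites without annotation: ",
         paste(utils::head(missing_ann, 5), collapse = ", "))
  }
  if (any(abundance < 0, na.rm = TRUE)) stop("abundances must be nonnegative")
  structure(list(abundance = abundance, groups = groups,
                 annotations = annotations),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("<metabolite_table> ", nrow(x$abundance), " samples x ",
      ncol(x$abundance), " metabolites; groups: ",
      paste(names(table(x$groups)), table(x$groups), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fill missing abundances with the group minimum
#'
#' Each missing cell is replaced by the minimum observed value of that
#' metabolite within the same group. Metabolite-group pairs with no observed
#' value at all stay missing; such metabolites are flagged in
#' `attr(, "untestable")` and reported with a warning.
#'
#' @param table a `metabolite_table`.
#' @return an imputed `metabolite_table`.
#' @export
impute_group_min <- function(table) {
  ab <- table$abundance
  untestable <- character(0)
  for (g in unique(table$groups)) {
    rows <- which(table$groups == g)
    block <- ab[rows, , drop = FALSE]
    mins <- suppressWarnings(apply(block, 2, min, na.rm = TRUE))
    for (j in which(colSums(is.na(block)) > 0)) {
      if (!is.finite(mins[j])) {
        untestable <- union(untestable, colnames(ab)[j])
        next
      }
      block[is.na(block[, j]), j] <- mins[j]
    }
    ab[rows, ] <- block
  }
  if (length(untestable)) {
    warning("metabolite(s) with an all-missing group excluded from testing: ",
            paste(untestable, collapse = ", "))
  }
  out <- table
  out$abundance <- ab
  attr(out, "untestable") <- untestable
  out
}

#' Welch's unequal-variance t test
#'
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with Welch-Satterthwaite
#' degrees of freedom and a two-tailed p value.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p` and `degenerate` (both variances zero).
#' @export
welch_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                df = na + nb - 2, p = if (equal) 1 else 0,
                degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tt, df = df, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Student's pooled-variance t test
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p` and `degenerate`.
#' @export
student_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                df = na + nb - 2, p = if (equal) 1 else 0, degenerate = TRUE))
  }
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tt, df = df, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Fold change and Cohen's d
#'
#' Fold change is `mean(case) / mean(control)`; Cohen's d uses the pooled
#' standard deviation with the `(na + nb - 2)` denominator.
#'
#' @param case,control numeric vectors.
#' @return list with `fold_change` (`NA` with `fc_undefined = TRUE` when the
#'   control mean is zero) and `cohens_d`.
#' @export
effect_sizes <- function(case, control) {
  mc <- mean(case); mk <- mean(control)
  fc_undefined <- mk == 0
  fc <- if (fc_undefined) NA_real_ else mc / mk
  na <- length(case); nb <- length(control)
  sp <- sqrt(((na - 1) * stats::var(case) + (nb - 1) * stats::var(control)) /
               (na + nb - 2))
  d <- if (sp == 0) {
    if (isTRUE(all.equal(mc, mk))) 0 else Inf * sign(mc - mk)
  } else (mc - mk) / sp
  list(fold_change = fc, cohens_d = d, fc_undefined = fc_undefined)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p values.
#' @return adjusted p values in the input order (monotone, `>=` raw, `<= 1`).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Per-metabolite differential statistics
#'
#' Computes, for every testable metabolite, group means, fold change
#' (case/control), the chosen t test, BH-adjusted p, Cohen's d, tier
#' (`significant` p <= 0.05, `trend` 0.05 < p <= 0.10, else `ns`) and
#' direction (`elevated` / `decreased` for non-`ns` tiers).
#'
#' @param table a `metabolite_table` (imputed first; see
#'   [impute_group_min()] — this function imputes when raw missing values
#'   are present).
#' @param case,control group labels; `case` is the numerator of the fold
#'   change.
#' @param test `"welch"` (default) or `"student"`.
#' @param p_sig,p_trend tier cutoffs (defaults 0.05 and 0.10).
#' @return a `metabolite_stats` data.frame.
#' @export
metabolite_stats <- function(table, case, control, test = c("welch", "student"),
                             p_sig = 0.05, p_trend = 0.10) {
  test <- match.arg(test)
  if (anyNA(table$abundance)) table <- impute_group_min(table)
  untestable <- attr(table, "untestable") %||% character(0)
  stopifnot(case %in% table$groups, control %in% table$groups)
  rows_a <- which(table$groups == case)
  rows_b <- which(table$groups == control)
  if (length(rows_a) < 2 || length(rows_b) < 2) {
    stop("need >= 2 samples per group")
  }
  ids <- setdiff(colnames(table$abundance), untestable)
  tester <- if (test == "welch") welch_test else student_test
  res <- lapply(ids, function(id) {
    a <- table$abundance[rows_a, id]
    b <- table$abundance[rows_b, id]
    tt <- tester(a, b)
    es <- effect_sizes(a, b)
    data.frame(metabolite_id = id, mean_case = mean(a), mean_control = mean(b),
               fold_change = es$fold_change, cohens_d = es$cohens_d,
               t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  tiers <- classify_tiers(out$p, out$fold_change, p_sig, p_trend)
  out$tier <- tiers$tier
  out$direction <- tiers$direction
  ann <- table$annotations
  out <- merge(out, ann, by = "metabolite_id", sort = FALSE)
  out <- out[match(ids, out$metabolite_id), ]
  rownames(out) <- NULL
  class(out) <- c("metabolite_stats", class(out))
  attr(out, "test") <- test
  out
}

#' Assign significance tiers and directions
#'
#' @param p raw p values.
#' @param fold_change case/control fold changes.
#' @param p_sig,p_trend tier cutoffs.
#' @return list of `tier` (`significant`/`trend`/`ns`) and `direction`
#'   (`elevated`/`decreased`/`""`; only non-`ns` metabolites get a direction).
#' @export
classify_tiers <- function(p, fold_change, p_sig = 0.05, p_trend = 0.10) {
  tier <- ifelse(p <= p_sig, "significant",
                 ifelse(p <= p_trend, "trend", "ns"))
  direction <- ifelse(tier == "ns" | is.na(fold_change), "",
                      ifelse(fold_change > 1, "elevated", "decreased"))
  list(tier = tier, direction = direction)
}

#' Subpathway enrichment ratio
#'
#' `E = (k/m) / ((n - k) / (N - m))`: the altered fraction inside a
#' subpathway relative to the altered fraction outside it.
#'
#' @param k altered metabolites in the subpathway.
#' @param m subpathway size (must exceed `min_size`).
#' @param n altered metabolites in the dataset.
#' @param N dataset size.
#' @param min_size minimum subpathway size (default 5, exclusive).
#' @return list with `E` and `undefined` flag (`n == k` with `N == m`).
#' @export
enrichment <- function(k, m, n, N, min_size = 5) {
  stopifnot(k >= 0, k <= m, k <= n, N >= m)
  if (m <= min_size) {
    return(list(E = NA_real_, undefined = FALSE, skipped = TRUE))
  }
  if (N == m) {
    return(list(E = NA_real_, undefined = TRUE, skipped = FALSE))
  }
  if (k == 0) return(list(E = 0, undefined = FALSE, skipped = FALSE))
  denom <- (n - k) / (N - m)
  if (denom == 0) {
    return(list(E = Inf, undefined = TRUE, skipped = FALSE))
  }
  list(E = (k / m) / denom, undefined = FALSE, skipped = FALSE)
}

#' Enrichment over all subpathways, per direction
#'
#' Altered metabolites are those in the `significant` tier, plus the `trend`
#' tier unless `strict`. `n` is direction-specific by default (the elevated
#' direction uses the total elevated count); `direction_specific_n = FALSE`
#' uses all altered metabolites as `n` for both directions.
#'
#' @param stats a `metabolite_stats` data.frame.
#' @param min_size minimum subpathway size (exclusive; default 5).
#' @param strict count only `significant` metabolites as altered.
#' @param direction_specific_n see description.
#' @return data.frame with `subpathway`, `direction`, `k`, `m`, `n`, `N`, `E`.
#' @export
subpathway_enrichment <- function(stats, min_size = 5, strict = FALSE,
                                  direction_specific_n = TRUE) {
  altered <- stats$tier == "significant" | (!strict & stats$tier == "trend")
  N <- nrow(stats)
  out <- NULL
  for (dir in c("elevated", "decreased")) {
    hits <- altered & stats$direction == dir
    n <- if (direction_specific_n) sum(hits) else sum(altered)
    for (sp in unique(stats$subpathway)) {
      in_sp <- stats$subpathway == sp
      m <- sum(in_sp)
      if (m <= min_size) next
      k <- sum(hits & in_sp)
      e <- enrichment(k, m, n, N, min_size)
      out <- rbind(out, data.frame(
        subpathway = sp, direction = dir, k = k, m = m, n = n, N = N,
        E = e$E, stringsAsFactors = FALSE))
    }
  }
  out[order(out$direction, -out$E), , drop = FALSE]
}

#' Overlap measured altered metabolites with model predictions
#'
#' Joins on HMDB id and labels each predicted metabolite with the
#' experiments that altered it (`Knockout`, `Drug treated`, `Both`).
#'
#' @param predicted character vector of HMDB ids predicted altered by the
#'   model.
#' @param knockout_altered,drug_altered character vectors of HMDB ids
#'   altered in each experiment.
#' @return list with `overlap` (data.frame `hmdb_id`, `experiment`) and
#'   `unmatched` (predicted ids with no HMDB-style id).
#' @export
overlap_with_predictions <- function(predicted, knockout_altered,
                                     drug_altered = character(0)) {
  has_id <- nzchar(predicted) & !is.na(predicted)
  unmatched <- predicted[!has_id]
  predicted <- unique(predicted[has_id])
  in_ko <- predicted %in% knockout_altered
  in_drug <- predicted %in% drug_altered
  hit <- in_ko | in_drug
  experiment <- ifelse(in_ko & in_drug, "Both",
                       ifelse(in_ko, "Knockout", "Drug treated"))
  list(
    overlap = data.frame(hmdb_id = predicted[hit],
                         experiment = experiment[hit],
                         stringsAsFactors = FALSE),
    unmatched = unmatched
  )
}

#' Read a metabolite table from CSV/TSV files
#'
#' @param abundance_path samples x metabolites table (first column = sample
#'   id); TSV or CSV by extension.
#' @param groups_path two-column table (sample_id, group).
#' @param annotations_path table with `metabolite_id`, `superpathway`,
#'   `subpathway`, optional `hmdb_id`.
#' @return a `metabolite_table`.
#' @export
read_metabolite_table <- function(abundance_path, groups_path,
                                  annotations_path) {
  readf <- function(p) {
    if (grepl("\\.csv$", p, ignore.case = TRUE)) {
      utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  ab <- readf(abundance_path)
  rn <- as.character(ab[[1]])
  ab <- as.matrix(ab[, -1, drop = FALSE])
  rownames(ab) <- rn
  groups_tab <- readf(groups_path)
  groups <- stats::setNames(as.character(groups_tab[[2]]),
                            as.character(groups_tab[[1]]))
  metabolite_table(ab, groups, readf(annotations_path))
}
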