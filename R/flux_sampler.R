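# Uniform sampling of the feasible flux polytope.
#
# Artificial-centering hit-and-run (ACHR): warmup points come from
# per-reaction min/max optimisations (FVA vertices); each step picks a
# retained point, draws the direction through the running center, intersects
# the chord with the box constraints, and moves the current point to a
# uniform position on the chord. Directions are differences of feasible
# points so they stay in the null space of S; they are re-projected onto the
# null space each step to stop round-off from accumulating mass-balance
# error.

#' Warmup points for hit-and-run sampling
#'
#' Alternating per-reaction minimisations and maximisations at
#' `fraction_of_optimum = 0`, i.e. extreme-ish vertices of the flux polytope.
#'
#' @param model a `metabolic_model`.
#' @param count number of points; at least `2 * n_reactions` is recommended
#'   so every reaction contributes both extremes (points cycle through
#'   reactions when `count` is larger than `2 * n_reactions`).
#' @return list with `status`; when `"optimal"`, `points` is a
#'   `count x n_reactions` matrix with reaction-id column names.
#' @export
warmup_points <- function(model, count = max(2L * n_reactions(model), 50L)) {
  nr <- n_reactions(model)
  Svec <- numeric(n_metabolites(model))
  pts <- matrix(NA_real_, count, nr,
                dimnames = list(NULL, model$reactions$id))
  for (k in seq_len(count)) {
    j <- ((k - 1L) %/% 2L) %% nr + 1L
    c_vec <- numeric(nr)
    c_vec[j] <- 1
    res <- solve_lp(c_vec, model$stoichiometry, Svec,
                    model$reactions$lower_bound, model$reactions$upper_bound,
                    maximize = (k %% 2L == 0L))
    if (res$status != "optimal") {
      return(list(status = res$status, points = NULL))
    }
    pts[k, ] <- res$solution
  }
  list(status = "optimal", points = pts)
}

#' Sample feasible flux states with artificial-centering hit-and-run
#'
#' @param model a `metabolic_model` (feasible).
#' @param n_samples number of flux states to emit (>= 2).
#' @param seed integer RNG seed; mandatory for reproducibility.
#' @param thinning chain steps between emitted samples (default 100). The
#'   per-coordinate integrated autocorrelation time of the chain grows with
#'   the polytope dimension (roughly 10-40 steps for 5-20 dimensional
#'   polytopes), so thinning should be a small multiple of that when sample
#'   independence matters (e.g. for downstream significance tests).
#' @param burnin chain steps discarded before the first emission (default
#'   `5 * thinning`); removes the bias of starting at a warmup vertex.
#' @param warmup number of warmup points (default `max(2 * dim, 50)`).
#' @param eps_mass,eps_bound tolerances used when validating emitted states.
#' @return a `flux_sample_set`: list with `condition`, `samples`
#'   (n_samples x n_reactions matrix), `seed`, `normalization` (`"none"`),
#'   `chain` metadata, and `degenerate` flag (polytope of dimension 0).
#' @export
sample_fluxes <- function(model, n_samples, seed, thinning = 100L,
                          burnin = 5L * thinning, warmup = NULL,
                          condition = model$id,
                          eps_mass = 1e-6, eps_bound = 1e-9) {
  stopifnot(n_samples >= 2)
  if (missing(seed) || is.null(seed)) stop("a seed is required for sampling")
  nr <- n_reactions(model)
  if (is.null(warmup)) warmup <- max(2L * nr, 50L)
  wu <- warmup_points(model, warmup)
  if (wu$status != "optimal") {
    stop("cannot sample: model is ", wu$status)
  }
  pts <- wu$points
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound

  # null-space projector of S (guards against drift out of S v = 0)
  sv <- svd(model$stoichiometry, nu = 0, nv = nr)
  d <- sv$d
  rank <- sum(d > max(dim(model$stoichiometry)) * max(d, 0) * 1e-12)
  degenerate <- FALSE
  if (rank >= nr || max(pts) - min(pts) < 1e-12 ||
      all(apply(pts, 2, function(x) max(x) - min(x)) < 1e-10)) {
    # dimension-0 polytope: the unique point, replicated
    out <- pts[rep(1L, n_samples), , drop = FALSE]
    warning("flux polytope has dimension 0; returning copies of the unique point")
    return(flux_sample_set(out, condition, seed,
                           list(warmup = warmup, thinning = thinning,
                                iterations = 0L),
                           degenerate = TRUE))
  }
  N <- sv$v[, (rank + 1L):nr, drop = FALSE]  # orthonormal null-space basis

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))

  center <- colMeans(pts)
  x <- pts[1L, ]
  samples <- matrix(NA_real_, n_samples, nr,
                    dimnames = list(NULL, model$reactions$id))
  n_pts <- nrow(pts)
  total_pts <- n_pts
  emitted <- 0L
  iters <- 0L
  burnin <- as.integer(burnin)
  max_iters <- burnin + n_samples * thinning * 10L  # safety valve
  while (emitted < n_samples && iters < max_iters) {
    iters <- iters + 1L
    ref <- pts[sample.int(n_pts, 1L), ]
    dvec <- ref - center
    # re-project onto null(S) and normalise
    dvec <- as.numeric(N %*% crossprod(N, dvec))
    # kill numerical noise in coordinates that are genuinely fixed, so the
    # walker never drifts along them
    dvec[abs(dvec) < 1e-11] <- 0
    dn <- sqrt(sum(dvec^2))
    if (dn < 1e-12) next
    dvec <- dvec / dn
    # chord of the box along dvec through x
    pos <- dvec > 0
    neg <- dvec < 0
    amax <- suppressWarnings(min(c((ub[pos] - x[pos]) / dvec[pos],
                                   (lb[neg] - x[neg]) / dvec[neg], Inf)))
    amin <- suppressWarnings(max(c((lb[pos] - x[pos]) / dvec[pos],
                                   (ub[neg] - x[neg]) / dvec[neg], -Inf)))
    if (!is.finite(amax) || !is.finite(amin) || amax - amin < 1e-10) next
    # stay strictly inside the chord so the walker never sits exactly on a
    # face (a point on a vertex would strangle later chords)
    margin <- 1e-9 * (amax - amin)
    alpha <- stats::runif(1, amin + margin, amax - margin)
    x <- x + alpha * dvec
    # artificial centering during burn-in only: the running center adapts
    # while the chain finds the bulk, then freezes so the post-burn-in chain
    # has a state-independent direction distribution (a proper
    # uniform-invariant Markov kernel; letting the center keep adapting
    # injects chain-level mean drift that inflates downstream F statistics)
    if (iters <= burnin) {
      total_pts <- total_pts + 1L
      center <- center + (x - center) / total_pts
    }
    if (iters > burnin && (iters - burnin) %% thinning == 0L) {
      emitted <- emitted + 1L
      samples[emitted, ] <- x
    }
  }
  if (emitted < n_samples) stop("sampler failed to emit requested samples")
  set <- flux_sample_set(samples, condition, seed,
                         list(warmup = warmup, thinning = thinning,
                              burnin = burnin, iterations = iters),
                         degenerate = FALSE)
  validate_sample_set(set, model, eps_mass, eps_bound)
  set
}

flux_sample_set <- function(samples, condition, seed, chain,
                            normalization = "none", degenerate = FALSE,
                            zero_rows = integer(0)) {
  structure(
    list(condition = condition, samples = samples, seed = seed,
         chain = chain, normalization = normalization,
         degenerate = degenerate, zero_rows = zero_rows),
    class = "flux_sample_set"
  )
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("<flux_sample_set> condition=", x$condition,
      " n=", nrow(x$samples), " reactions=", ncol(x$samples),
      " seed=", x$seed, " normalization=", x$normalization, "\n", sep = "")
  invisible(x)
}

validate_sample_set <- function(set, model, eps_mass = 1e-6, eps_bound = 1e-9) {
  resid <- max(abs(model$stoichiometry %*% t(set$samples)))
  if (resid > eps_mass) {
    stop("sample set violates mass balance: max ||S v||_inf = ", format(resid))
  }
  lo <- sweep(set$samples, 2, model$reactions$lower_bound, "-")
  hi <- sweep(-set$samples, 2, model$reactions$upper_bound, "+")
  if (min(lo) < -eps_bound || min(hi) < -eps_bound) {
    stop("sample set violates bounds")
  }
  invisible(TRUE)
}

#' Normalise flux samples
#'
#' `l1` divides each sampled flux state by its total absolute flux so states
#' are comparable across conditions whose overall flux capacity differs
#' (e.g. after a knockout). All-zero rows are left untouched and flagged in
#' `zero_rows`.
#'
#' @param set a `flux_sample_set`.
#' @param mode `"l1"` or `"none"`.
#' @return a `flux_sample_set` with `normalization` recorded.
#' @export
normalize_samples <- function(set, mode = c("l1", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(set)
  totals <- rowSums(abs(set$samples))
  zero <- which(totals == 0)
  scale <- ifelse(totals == 0, 1, totals)
  out <- set
  out$samples <- set$samples / scale
  out$normalization <- "l1"
  out$zero_rows <- zero
  out
}

#' Persist a sample set as a TSV plus JSON sidecar
#'
#' @param set a `flux_sample_set`.
#' @param path TSV output path; the sidecar is written to `paste0(path, ".json")`.
#' @export
write_sample_set <- function(set, path) {
  utils::write.table(set$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(condition = set$condition, seed = set$seed, chain = set$chain,
         normalization = set$normalization,
         sign_convention = "positive exchange flux = secretion, negative = uptake"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sample set written by [write_sample_set()]
#'
#' @param path TSV path.
#' @return a `flux_sample_set`.
#' @export
read_sample_set <- function(path) {
  samples <- as.matrix(utils::read.delim(path, check.names = FALSE))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  flux_sample_set(samples, meta$condition, meta$seed, as.list(meta$chain),
                  normalization = meta$normalization %||% "none")
}
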