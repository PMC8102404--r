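# Classification of elevated vs decreased lipids from molecular descriptors.
#
# Feature selection: correlation pruning (|r| > cutoff drops the
# lower-ranked member of the pair) followed by information-gain ranking on
# equal-frequency 4-bin discretisation. Class balancing (down/up/combined)
# happens inside every leave-one-out fold, never touching the held-out
# molecule, and features are standardised with training-fold statistics only
# — both choices prevent resampling/scaling leakage from inflating accuracy.
#
# The four model types (decision tree, random forest, k-nearest neighbours,
# logistic regression) are implemented here: CART with Gini impurity and
# min-leaf 2, a bagged forest with sqrt(p) feature subsampling, majority-vote
# kNN (k = 5), and `stats::glm` logistic regression.

#' Build molecule records from SMILES
#'
#' @param table data.frame with columns `name`, `smiles`, `direction`
#'   (`elevated`/`decreased`) and `subpathway`.
#' @return a `molecule_records` object: the input plus a `descriptors`
#'   matrix (rows = molecules).
#' @export
molecule_records <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "smiles", "direction", "subpathway") %in% names(table)))
  bad <- !table$direction %in% c("elevated", "decreased")
  if (any(bad)) stop("direction must be 'elevated' or 'decreased'; offending: ",
                     paste(table$name[bad], collapse = ", "))
  desc <- t(vapply(seq_len(nrow(table)), function(i) {
    compute_descriptors(table$smiles[i], name = table$name[i])
  }, compute_descriptors("C")))
  rownames(desc) <- table$name
  if (anyNA(desc)) stop("descriptor matrix contains missing values")
  structure(list(table = table, descriptors = desc),
            class = "molecule_records")
}

#' @export
print.molecule_records <- function(x, ...) {
  cat("<molecule_records> ", nrow(x$table), " molecules (",
      sum(x$table$direction == "elevated"), " elevated / ",
      sum(x$table$direction == "decreased"), " decreased), ",
      ncol(x$descriptors), " descriptors\n", sep = "")
  invisible(x)
}

#' Read molecule records from a TSV (name, smiles, direction, subpathway)
#'
#' @param path TSV path with header.
#' @return a `molecule_records` object.
#' @export
read_molecule_tsv <- function(path) {
  molecule_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# equal-frequency discretisation into `bins` bins (constant columns give a
# single bin)
discretize_ef <- function(x, bins = 4) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(qs) < 2) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

#' Information gain of the class label for one feature
#'
#' @param x numeric feature.
#' @param y class labels.
#' @param bins equal-frequency bins (default 4).
#' @return information gain in bits.
#' @export
information_gain <- function(x, y, bins = 4) {
  h <- entropy_bits(y)
  d <- discretize_ef(x, bins)
  cond <- 0
  for (lev in unique(d)) {
    sel <- d == lev
    cond <- cond + mean(sel) * entropy_bits(y[sel])
  }
  h - cond
}

#' Select discriminative features
#'
#' Drops the lower-ranked member of every feature pair with
#' `|Pearson r| > corr_cutoff`, ranks survivors by information gain
#' (equal-frequency 4-bin discretisation), and returns the top
#' `target_count`. Ties in ranking break by descriptor name (stable order).
#'
#' @param records a `molecule_records` object.
#' @param target_count number of features to keep (default 6, >= 2).
#' @param corr_cutoff absolute-correlation pruning threshold (default 0.9).
#' @return character vector of selected feature names (attribute `ranking`
#'   carries the full ranked table).
#' @export
select_features <- function(records, target_count = 6, corr_cutoff = 0.9) {
  stopifnot(target_count >= 2)
  X <- records$descriptors
  y <- records$table$direction
  # rank all features first (information gain), used both to break
  # correlation ties and for the final ordering
  gains <- vapply(colnames(X), function(f) information_gain(X[, f], y),
                  numeric(1))
  ord <- order(-gains, colnames(X))  # tie-break: name, stable
  ranked <- colnames(X)[ord]
  keep <- ranked
  # correlation pruning: walk pairs, drop lower-ranked member
  cors <- suppressWarnings(stats::cor(X))
  cors[is.na(cors)] <- 0
  dropped <- character(0)
  for (i in seq_along(ranked)) {
    fi <- ranked[i]
    if (fi %in% dropped) next
    for (j in seq_along(ranked)) {
      if (j <= i) next
      fj <- ranked[j]
      if (fj %in% dropped) next
      if (abs(cors[fi, fj]) > corr_cutoff) dropped <- c(dropped, fj)
    }
  }
  keep <- setdiff(ranked, dropped)
  if (length(keep) < target_count) {
    warning("only ", length(keep), " features survive correlation pruning; ",
            "returning all of them")
    target_count <- length(keep)
  }
  out <- keep[seq_len(target_count)]
  attr(out, "ranking") <- data.frame(feature = ranked,
                                     information_gain = gains[ord],
                                     dropped = ranked %in% dropped,
                                     stringsAsFactors = FALSE)
  out
}

#' Balance a two-class record set
#'
#' `downsample` reduces the majority class to the minority size;
#' `upsample` resamples the minority with replacement to the majority size;
#' `combined` brings both classes to the (rounded) geometric mean of the two
#' sizes. Deterministic under `seed`.
#'
#' @param labels class label vector.
#' @param scheme `"downsample"`, `"upsample"` or `"combined"`.
#' @param seed integer seed.
#' @return integer vector of row indices into the input.
#' @export
balance_indices <- function(labels, scheme = c("downsample", "upsample", "combined"),
                            seed) {
  scheme <- match.arg(scheme)
  tab <- table(labels)
  if (length(tab) != 2 || any(tab == 0)) {
    stop("balancing requires two non-empty classes; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  rng <- local_rng(seed)
  sizes <- as.integer(tab)
  target <- switch(scheme,
                   downsample = min(sizes),
                   upsample = max(sizes),
                   combined = as.integer(round(sqrt(prod(as.numeric(sizes))))))
  idx <- integer(0)
  for (cl in names(tab)) {
    rows <- which(labels == cl)
    if (length(rows) == target) {
      take <- rows
    } else if (length(rows) > target) {
      take <- rng$sample(rows, target)
    } else {
      take <- c(rows, rng$sample(rows, target - length(rows), replace = TRUE))
    }
    idx <- c(idx, take)
  }
  idx
}

# seed-scoped RNG that restores the caller's state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  use <- function(f) {
    function(...) {
      outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", state, globalenv())
      out <- f(...)
      state <<- get(".Random.seed", globalenv())
      if (!is.null(outer)) assign(".Random.seed", outer, globalenv())
      out
    }
  }
  list(sample = use(sample), runif = use(stats::runif),
       rnorm = use(stats::rnorm), sample_int = use(sample.int))
}

## ---- classifiers -----------------------------------------------------------

train_classifier <- function(X, y, model_name, seed) {
  y <- factor(y)
  switch(model_name,
    logistic = {
      df <- as.data.frame(X)
      df$.y <- y
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      list(kind = "logistic", fit = fit, levels = levels(y))
    },
    knn = list(kind = "knn", X = X, y = y, k = 5L),
    decision_tree = list(kind = "tree", fit = cart_fit(X, y, seed = seed),
                         levels = levels(y)),
    random_forest = {
      rng <- local_rng(seed)
      n <- nrow(X); p <- ncol(X)
      mtry <- max(1L, floor(sqrt(p)))
      trees <- lapply(seq_len(50L), function(b) {
        rows <- rng$sample_int(n, n, replace = TRUE)
        feats <- rng$sample(colnames(X), mtry)
        list(tree = cart_fit(X[rows, feats, drop = FALSE], y[rows],
                             seed = seed + b),
             feats = feats)
      })
      list(kind = "forest", trees = trees, levels = levels(y))
    },
    stop("unknown model '", model_name, "'; supported: decision_tree, ",
         "random_forest, knn, logistic")
  )
}

predict_classifier <- function(fit, Xnew) {
  switch(fit$kind,
    logistic = {
      pr <- stats::predict(fit$fit, newdata = as.data.frame(Xnew),
                           type = "response")
      factor(ifelse(pr > 0.5, fit$levels[2], fit$levels[1]),
             levels = fit$levels)
    },
    knn = {
      lv <- levels(fit$y)
      preds <- apply(Xnew, 1, function(row) {
        d2 <- colSums((t(fit$X) - row)^2)
        nn <- order(d2)[seq_len(min(fit$k, length(d2)))]
        votes <- table(fit$y[nn])
        names(votes)[which.max(votes)]  # ties: first level (stable)
      })
      factor(preds, levels = lv)
    },
    tree = factor(cart_predict(fit$fit, Xnew), levels = fit$levels),
    forest = {
      votes <- sapply(fit$trees, function(tr) {
        cart_predict(tr$tree, Xnew[, tr$feats, drop = FALSE])
      })
      if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(Xnew))
      preds <- apply(votes, 1, function(v) {
        tb <- table(v)
        names(tb)[which.max(tb)]
      })
      factor(preds, levels = fit$levels)
    }
  )
}

# CART with Gini impurity; unlimited depth, min-leaf 2.
cart_fit <- function(X, y, min_leaf = 2L, seed = 0L) {
  grow <- function(rows) {
    ys <- y[rows]
    tab <- table(ys)
    majority <- names(tab)[which.max(tab)]
    if (length(unique(ys)) == 1L || length(rows) < 2L * min_leaf) {
      return(list(leaf = TRUE, label = majority))
    }
    best <- NULL
    n <- length(rows)
    y01 <- as.integer(ys == levels(y)[1])
    for (f in colnames(X)) {
      x <- X[rows, f]
      o <- order(x)
      xs <- x[o]; ys1 <- y01[o]
      cum1 <- cumsum(ys1)
      tot1 <- cum1[n]
      nl <- seq_len(n - 1)
      # candidate split after position i (xs[i] < xs[i+1])
      valid <- xs[nl] < xs[nl + 1] & nl >= min_leaf & (n - nl) >= min_leaf
      if (!any(valid)) next
      p1l <- cum1[nl] / nl
      p1r <- (tot1 - cum1[nl]) / (n - nl)
      gini <- nl / n * 2 * p1l * (1 - p1l) + (n - nl) / n * 2 * p1r * (1 - p1r)
      gini[!valid] <- Inf
      i <- which.min(gini)
      if (is.null(best) || gini[i] < best$gini - 1e-12) {
        best <- list(gini = gini[i], feature = f,
                     threshold = (xs[i] + xs[i + 1]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, label = majority))
    parent_gini <- {
      p <- mean(y01)
      2 * p * (1 - p)
    }
    if (best$gini >= parent_gini - 1e-12) {
      return(list(leaf = TRUE, label = majority))
    }
    left_rows <- rows[X[rows, best$feature] <= best$threshold]
    right_rows <- rows[X[rows, best$feature] > best$threshold]
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         left = grow(left_rows), right = grow(right_rows),
         label = majority)
  }
  grow(seq_len(nrow(X)))
}

cart_predict <- function(tree, Xnew) {
  apply(Xnew, 1, function(row) {
    node <- tree
    while (!node$leaf) {
      node <- if (row[[node$feature]] <= node$threshold) node$left else node$right
    }
    node$label
  })
}

## ---- leave-one-out evaluation ---------------------------------------------

#' Leave-one-out evaluation with in-fold balancing
#'
#' For every molecule: hold it out, balance the remaining records, train the
#' named model on the selected features (standardised with training-fold
#' statistics), predict the held-out label. Reports accuracy, the 2x2
#' confusion matrix and the misclassified molecules with their subpathways.
#'
#' @param records a `molecule_records` object.
#' @param features character vector of feature names (see
#'   [select_features()]).
#' @param model_name `"decision_tree"`, `"random_forest"`, `"knn"` or
#'   `"logistic"`.
#' @param seed integer seed driving balancing and any model randomness.
#' @param scheme balancing scheme, see [balance_indices()].
#' @return a `classification_report` list: `model`, `scheme`, `seed`,
#'   `accuracy`, `confusion` (2x2), `predictions` (per-molecule data.frame),
#'   `misclassified` (with subpathways).
#' @export
loo_evaluate <- function(records, features, model_name,
                         seed, scheme = c("downsample", "upsample", "combined")) {
  scheme <- match.arg(scheme)
  X <- records$descriptors[, features, drop = FALSE]
  y <- factor(records$table$direction, levels = c("decreased", "elevated"))
  n <- nrow(X)
  preds <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    bal <- balance_indices(as.character(ytr), scheme, seed = seed + i)
    Xtr <- Xtr[bal, , drop = FALSE]
    ytr <- ytr[bal]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xh <- sweep(sweep(X[i, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- train_classifier(Xs, ytr, model_name, seed = seed + i)
    preds[i] <- as.character(predict_classifier(fit, Xh))
  }
  preds <- factor(preds, levels = levels(y))
  confusion <- table(truth = y, predicted = preds)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  mis <- which(preds != y)
  structure(list(
    model = model_name, scheme = scheme, seed = seed,
    accuracy = accuracy, confusion = confusion,
    predictions = data.frame(name = records$table$name,
                             truth = as.character(y),
                             predicted = as.character(preds),
                             stringsAsFactors = FALSE),
    misclassified = data.frame(name = records$table$name[mis],
                               subpathway = records$table$subpathway[mis],
                               truth = as.character(y)[mis],
                               stringsAsFactors = FALSE)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> model=", x$model, " scheme=", x$scheme,
      " seed=", x$seed, "\n", sep = "")
  cat(sprintf("  LOO accuracy: %.1f%% (%d/%d)\n", 100 * x$accuracy,
              sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

## ---- FreeViz ---------------------------------------------------------------

#' FreeViz-style force-optimised linear projection
#'
#' Each feature gets a 2-D anchor; the embedding is the standardised-feature
#' matrix times the anchor matrix. Anchors start on the unit circle (seeded
#' random rotation) and follow gradient steps on a force objective:
#' same-class pairs attract proportionally to distance, different-class
#' pairs repel proportionally to 1/distance. Anchors are renormalised each
#' step so the longest has unit length. Optimisation stops when the
#' objective improves by less than `tol` or after `max_iter` steps.
#'
#' @param records a `molecule_records` object.
#' @param features feature names (>= 2).
#' @param seed integer seed for anchor initialisation.
#' @param max_iter maximum gradient steps (default 200).
#' @param step gradient step size (default 0.05).
#' @param tol convergence tolerance on the objective (default 1e-6).
#' @return list with `anchors` (features x 2), `embedding` (molecules x 2),
#'   `objective` trace, `converged`.
#' @export
freeviz_project <- function(records, features, seed, max_iter = 200,
                            step = 0.05, tol = 1e-6) {
  if (length(features) < 2) stop("FreeViz needs at least 2 features")
  X <- records$descriptors[, features, drop = FALSE]
  X <- scale(X)
  X[is.nan(X)] <- 0
  y <- factor(records$table$direction)
  n <- nrow(X); p <- ncol(X)
  rng <- local_rng(seed)
  theta <- rng$runif(p, 0, 2 * pi)
  A <- cbind(cos(theta), sin(theta))
  same <- outer(as.integer(y), as.integer(y), "==")
  diag(same) <- NA  # exclude self-pairs
  objective <- function(E) {
    D2 <- as.matrix(stats::dist(E))^2
    attract <- sum(D2[same & !is.na(same)]) / 2
    repel <- sum(1 / sqrt(D2[!same & !is.na(same)] + 1e-9)) / 2
    attract + repel
  }
  gradient <- function(A) {
    E <- X %*% A
    G <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      diff <- sweep(E, 2, E[i, ], "-")   # E_j - E_i
      d <- sqrt(rowSums(diff^2)) + 1e-9
      w <- ifelse(same[i, ], 2, -1 / d^3)  # d(attract)/dE, d(repel)/dE
      w[i] <- 0
      w[is.na(w)] <- 0
      G[i, ] <- -colSums(diff * w)  # gradient wrt E_i
    }
    crossprod(X, G) / n
  }
  renorm <- function(A) A / max(sqrt(rowSums(A^2)), 1e-9)
  A <- renorm(A)
  obj_cur <- objective(X %*% A)
  obj_trace <- obj_cur
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Ag <- gradient(A)
    gn <- max(sqrt(rowSums(Ag^2)))
    if (gn < 1e-12) { converged <- TRUE; break }
    # move anchors by at most `step` in anchor units, monotone with
    # backtracking: reject uphill moves and halve the step
    A_new <- renorm(A - (step / gn) * Ag)
    obj_new <- objective(X %*% A_new)
    if (obj_new > obj_cur) {
      step <- step / 2
      if (step < 1e-6) { converged <- TRUE; break }
      next
    }
    improved <- obj_cur - obj_new
    A <- A_new
    obj_cur <- obj_new
    obj_trace <- c(obj_trace, obj_cur)
    if (improved < tol) { converged <- TRUE; break }
  }
  rownames(A) <- features
  colnames(A) <- c("x", "y")
  E <- X %*% A
  rownames(E) <- records$table$name
  colnames(E) <- c("x", "y")
  list(anchors = A, embedding = E, objective = obj_trace,
       converged = converged)
}
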