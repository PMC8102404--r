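# A small two-feature record set with controllable separation, used to test
# selection/balancing/validation without descriptor computation cost.
fake_records <- function(n1 = 30, n2 = 30, sep = 3, seed = 1, extra = NULL) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n1, 0), rnorm(n1, 0)),
             cbind(rnorm(n2, sep), rnorm(n2, 0)))
  colnames(X) <- c("f1", "f2")
  if (!is.null(extra)) X <- cbind(X, extra)
  tab <- data.frame(
    name = sprintf("m%03d", seq_len(n1 + n2)),
    smiles = "C",
    direction = rep(c("decreased", "elevated"), c(n1, n2)),
    subpathway = rep(c("sp1", "sp2"), length.out = n1 + n2),
    stringsAsFactors = FALSE)
  structure(list(table = tab, descriptors = X), class = "molecule_records")
}

test_that("correlation pruning drops duplicated features", {
  r <- fake_records()
  r$descriptors <- cbind(r$descriptors, f1_copy = r$descriptors[, "f1"])
  keep <- select_features(r, target_count = 2, corr_cutoff = 0.9)
  expect_length(keep, 2)
  expect_false(all(c("f1", "f1_copy") %in% keep))
})

test_that("a perfect predictor ranks first with gain = class entropy", {
  r <- fake_records(20, 20, sep = 0)
  indicator <- as.numeric(r$table$direction == "elevated")
  r$descriptors <- cbind(r$descriptors, oracle_feature = indicator)
  keep <- select_features(r, target_count = 2)
  expect_identical(keep[1], "oracle_feature")
  gain <- information_gain(indicator, r$table$direction)
  expect_equal(gain, 1)   # balanced two-class entropy is 1 bit
})

test_that("ring count survives selection when it separates the classes", {
  recs <- make_lipid_classes(n_elevated = 30, n_decreased = 20, seed = 5)
  # restrict the panel to weakly redundant features plus nof_Rings
  sub <- recs
  sub$descriptors <- recs$descriptors[, c("nof_Rings", "nof_RotB", "nof_OH",
                                          "nof_COOH", "tpsa", "logp_estimate",
                                          "n_nitrogens", "hbd")]
  keep <- select_features(sub, target_count = 6)
  expect_true("nof_Rings" %in% keep)
})

test_that("balancing schemes hit the documented sizes deterministically", {
  labels <- rep(c("elevated", "decreased"), c(86, 40))
  down <- balance_indices(labels, "downsample", seed = 1)
  expect_equal(as.integer(table(labels[down])), c(40L, 40L))
  up <- balance_indices(labels, "upsample", seed = 1)
  expect_equal(as.integer(table(labels[up])), c(86L, 86L))
  comb <- balance_indices(labels, "combined", seed = 1)
  expect_equal(as.integer(table(labels[comb])),
               rep(round(sqrt(86 * 40)), 2L))
  # deterministic under the seed; already-balanced input unchanged
  expect_identical(down, balance_indices(labels, "downsample", seed = 1))
  even <- rep(c("elevated", "decreased"), each = 10)
  expect_identical(sort(balance_indices(even, "downsample", seed = 2)), 1:20)
  expect_error(balance_indices(rep("elevated", 5), "downsample", seed = 1),
               "two non-empty classes")
})

test_that("LOO accuracy is high on separable data for every model", {
  r <- fake_records(40, 40, sep = 6, seed = 2)
  for (m in c("logistic", "knn", "decision_tree", "random_forest")) {
    rep_ <- loo_evaluate(r, c("f1", "f2"), m, seed = 4)
    expect_gte(rep_$accuracy, if (m == "logistic") 0.95 else 0.9)
    expect_equal(sum(rep_$confusion), 80)
    expect_equal(sum(diag(rep_$confusion)) / sum(rep_$confusion),
                 rep_$accuracy)
  }
})

test_that("label permutation and constant features collapse to chance", {
  r <- fake_records(40, 40, sep = 6, seed = 3)
  set.seed(9)
  r$table$direction <- sample(r$table$direction)
  perm <- loo_evaluate(r, c("f1", "f2"), "logistic", seed = 5)
  expect_gte(perm$accuracy, 0.30)
  expect_lte(perm$accuracy, 0.70)

  const <- fake_records(30, 30, sep = 0, seed = 4)
  const$descriptors[, "f1"] <- 1
  flat <- loo_evaluate(const, c("f1", "f2"), "knn", seed = 6)
  expect_gte(flat$accuracy, 0.25)
  expect_lte(flat$accuracy, 0.75)
})

test_that("misclassified molecules are reported with subpathways", {
  r <- fake_records(20, 20, sep = 0.5, seed = 5)
  rep_ <- loo_evaluate(r, c("f1", "f2"), "knn", seed = 7)
  expect_true(nrow(rep_$misclassified) > 0)
  expect_named(rep_$misclassified, c("name", "subpathway", "truth"))
  expect_error(loo_evaluate(r, c("f1", "f2"), "svm", seed = 1),
               "unknown model.*logistic")
})

test_that("FreeViz pulls the separating feature's anchor outward", {
  r <- fake_records(30, 30, sep = 5, seed = 6)
  fv <- freeviz_project(r, c("f1", "f2"), seed = 8)
  expect_gt(sqrt(sum(fv$anchors["f1", ]^2)),
            2 * sqrt(sum(fv$anchors["f2", ]^2)))
  # determinism
  fv2 <- freeviz_project(r, c("f1", "f2"), seed = 8)
  expect_identical(fv$anchors, fv2$anchors)
  expect_identical(fv$embedding, fv2$embedding)
  expect_error(freeviz_project(r, "f1", seed = 1), "at least 2")
})

test_that("FreeViz centroids coincide under random labels", {
  r <- fake_records(40, 40, sep = 0, seed = 7)
  fv <- freeviz_project(r, c("f1", "f2"), seed = 9)
  E <- fv$embedding
  g <- r$table$direction
  cent_d <- colMeans(E[g == "decreased", , drop = FALSE])
  cent_e <- colMeans(E[g == "elevated", , drop = FALSE])
  spread <- mean(sqrt(rowSums(sweep(E, 2, colMeans(E))^2)))
  expect_lt(sqrt(sum((cent_d - cent_e)^2)), spread)
})
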