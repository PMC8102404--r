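small_table <- function(ab = NULL) {
  if (is.null(ab)) {
    ab <- matrix(c(2, NA, 3, 5, 4, 6), nrow = 6, ncol = 1,
                 dimnames = list(c(paste0("WT_", 1:3), paste0("KO_", 1:3)),
                                 "m1"))
  }
  groups <- stats::setNames(rep(c("WT", "KO"), each = 3),
                            c(paste0("WT_", 1:3), paste0("KO_", 1:3)))
  ann <- data.frame(metabolite_id = colnames(ab), superpathway = "Lipid",
                    subpathway = "SP1")
  metabolite_table(ab[, , drop = FALSE], groups, ann)
}

test_that("group-minimum imputation fills only missing cells", {
  tab <- small_table()
  out <- impute_group_min(tab)
  expect_equal(unname(out$abundance[, "m1"]), c(2, 2, 3, 5, 4, 6))
  # observed cells never change; idempotent on a complete table
  out2 <- impute_group_min(out)
  expect_identical(out2$abundance, out$abundance)

  # an all-missing group excludes the metabolite with a warning
  ab <- matrix(c(NA, NA, NA, 5, 4, 6), nrow = 6,
               dimnames = list(rownames(tab$abundance), "m1"))
  expect_warning(bad <- impute_group_min(small_table(ab)), "all-missing")
  expect_identical(attr(bad, "untestable"), "m1")
})

test_that("Welch and Student t tests match stats::t.test to 1e-9", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  w <- welch_test(a, b)
  expect_equal(w$t, -1)
  expect_equal(w$p, 0.3466, tolerance = 1e-4)
  set.seed(33)
  for (rep in 1:50) {
    a <- rlnorm(sample(3:12, 1))
    b <- rlnorm(sample(3:12, 1), meanlog = runif(1, -1, 1),
                sdlog = runif(1, 0.5, 2))
    w <- welch_test(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(w$p, ref$p.value, tolerance = 1e-9)
    s <- student_test(a, b)
    ref2 <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(s$t, unname(ref2$statistic), tolerance = 1e-9)
    expect_equal(s$p, ref2$p.value, tolerance = 1e-9)
  }
  # degenerate zero-variance paths
  expect_equal(welch_test(c(0, 0), c(0, 0))$p, 1)
  expect_true(welch_test(c(0, 0), c(0, 0))$degenerate)
  expect_equal(welch_test(c(1, 2), c(1, 2))$t,
               0, tolerance = 1e-12)
})

test_that("effect sizes follow the pooled-SD definitions", {
  es <- effect_sizes(c(3, 4, 5), c(1, 2, 3))
  expect_equal(es$cohens_d, 2)        # diff 2, pooled SD 1
  expect_equal(es$fold_change, 2)
  expect_equal(effect_sizes(c(0.5, 0.5), c(2, 2))$fold_change, 0.25)
  expect_equal(effect_sizes(c(1, 2), c(1, 2))$cohens_d, 0)
  zero <- effect_sizes(c(1, 2), c(0, 0))
  expect_true(zero$fc_undefined)
  expect_true(is.na(zero$fold_change))
})

test_that("BH adjustment matches p.adjust and the hand-computed example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(44)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("tiers and directions partition the tested metabolites", {
  tiers <- classify_tiers(c(0.07, 0.04, 0.2), c(1.4, 0.3, 2.0))
  expect_equal(tiers$tier, c("trend", "significant", "ns"))
  expect_equal(tiers$direction, c("elevated", "decreased", ""))
  # directional partition on a generated table
  mk <- make_metabolomics(n_metabolites = 80, seed = 9)
  st <- metabolite_stats(mk$table, "KO", "WT")
  expect_equal(sum(st$tier == "significant") + sum(st$tier == "trend") +
                 sum(st$tier == "ns"), nrow(st))
  expect_equal(sum(st$direction == "elevated") + sum(st$direction == "decreased"),
               sum(st$tier != "ns"))
  # BH-adjusted p >= raw p always
  expect_true(all(st$p_adj >= st$p - 1e-15))
})

test_that("enrichment ratio follows (k/m)/((n-k)/(N-m))", {
  expect_equal(enrichment(0, 10, 20, 100)$E, 0)
  # matched proportions give E = 1
  expect_equal(enrichment(5, 10, 50, 100)$E, 1)
  # the worked polyunsaturated-fatty-acid value: 11 of 19 altered among
  # 86 elevated out of 342 lipids
  expect_equal(enrichment(11, 19, 86, 342)$E, (11 / 19) / (75 / 323),
               tolerance = 1e-12)
  expect_true(enrichment(3, 6, 3, 6)$undefined)
  expect_true(enrichment(2, 5, 10, 50)$skipped)   # m <= 5 skipped
  # complement direction computes without error for valid inputs
  k <- 11; m <- 19; n <- 86; N <- 342
  comp <- enrichment(m - k, m, N - n, N)
  expect_false(comp$undefined)
})

test_that("subpathway enrichment respects direction-specific n and min size", {
  mk <- make_metabolomics(n_metabolites = 120, seed = 21, missing_rate = 0)
  st <- metabolite_stats(mk$table, "KO", "WT")
  en <- subpathway_enrichment(st)
  expect_true(all(en$m > 5))
  expect_true(all(en$k <= pmin(en$m, en$n)))
  expect_true(all(en$E >= 0 | is.na(en$E)))
  up <- en[en$direction == "elevated", ]
  expect_true(all(up$n == up$n[1]))   # shared direction-specific n
  # total-n mode uses significant+trend of both directions
  en2 <- subpathway_enrichment(st, direction_specific_n = FALSE)
  expect_true(all(en2$n >= up$n[1]))
})

test_that("prediction overlap labels experiments like the join table", {
  ov <- overlap_with_predictions(c("H1", "H2"), knockout_altered = "H2",
                                 drug_altered = character(0))
  expect_equal(ov$overlap$hmdb_id, "H2")
  expect_equal(ov$overlap$experiment, "Knockout")
  expect_equal(nrow(overlap_with_predictions("H9", "H1", "H2")$overlap), 0)
  both <- overlap_with_predictions("HMDB03073", "HMDB03073", "HMDB03073")
  expect_equal(both$overlap$experiment, "Both")
  unm <- overlap_with_predictions(c("", "H1"), "H1")
  expect_equal(unm$unmatched, "")
})

test_that("metabolite tables read from disk files", {
  mk <- make_metabolomics(n_metabolites = 15, seed = 2)
  dir <- withr::local_tempdir()
  ab <- data.frame(sample_id = rownames(mk$table$abundance),
                   mk$table$abundance, check.names = FALSE)
  utils::write.table(ab, file.path(dir, "ab.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(mk$table$groups), group = mk$table$groups),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mk$table$annotations, file.path(dir, "ann.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_metabolite_table(file.path(dir, "ab.tsv"),
                               file.path(dir, "groups.tsv"),
                               file.path(dir, "ann.tsv"))
  expect_equal(tab$abundance, mk$table$abundance)
  expect_identical(unname(tab$groups), unname(mk$table$groups))
})
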