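test_that("the two-group F test matches the hand ANOVA oracle", {
  # wt = (1,2,3), ko = (4,5,6): grand mean 3.5, SSB = 13.5, MSW = 1 -> F = 13.5
  res <- reaction_ftest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$F, 13.5)
  expect_equal(res$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  # identical vectors in both groups
  same <- reaction_ftest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)

  # zero within-group variance: equal means vs unequal means
  flat_eq <- reaction_ftest(c(2, 2), c(2, 2))
  expect_equal(flat_eq$F, 0)
  expect_equal(flat_eq$p, 1)
  expect_true(flat_eq$degenerate)
  flat_ne <- reaction_ftest(c(2, 2), c(3, 3))
  expect_equal(flat_ne$p, 0)
  expect_true(flat_ne$degenerate)
})

test_that("F equals the squared pooled t statistic", {
  set.seed(101)
  for (rep in 1:25) {
    a <- rnorm(sample(3:20, 1))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2))
    f <- reaction_ftest(a, b)
    t_pooled <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f$F, unname(t_pooled)^2, tolerance = 1e-9)
    expect_equal(f$p, stats::t.test(a, b, var.equal = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

make_set <- function(mat, condition = "x", seed = 1) {
  fluxlip:::flux_sample_set(mat, condition, seed, list())
}

test_that("altered calls combine the p threshold with the fold-change filter", {
  set.seed(7)
  n <- 500
  # reaction a: clear 0.4-fold drop; reaction b: significant but tiny shift;
  # reaction c: big fold change but noisy (not significant)
  wt <- cbind(a = rnorm(n, 1, 0.05), b = rnorm(n, 1, 0.05),
              c = rnorm(n, 0.001, 1))
  ko <- cbind(a = rnorm(n, 0.4, 0.05), b = rnorm(n, 1.02, 0.05),
              c = rnorm(n, 0.0012, 1))
  res <- call_altered_reactions(make_set(wt), make_set(ko))
  tab <- res$table
  expect_true(tab$altered[tab$reaction == "a"])
  expect_equal(tab$fold_change[tab$reaction == "a"], 0.4, tolerance = 0.05)
  expect_false(tab$altered[tab$reaction == "b"])   # p small, FC inside band
  expect_false(tab$altered[tab$reaction == "c"])   # FC outside band, p large
  # full table regardless of flags
  expect_equal(nrow(tab), 3)
})

test_that("identical models under two seeds give a null-calibrated table", {
  m <- box_model(c(4, 3, 2))
  s1 <- normalize_samples(sample_fluxes(m, 400, seed = 1, thinning = 5), "l1")
  s2 <- normalize_samples(sample_fluxes(m, 400, seed = 2, thinning = 5), "l1")
  res <- call_altered_reactions(s1, s2)
  expect_equal(sum(res$table$altered), 0)
})

test_that("null p-values are uniform at alpha 0.05 and 0.001 on mixed chains", {
  # dimension-2 boxes mix fast (autocorrelation time ~5 steps), so thinning
  # 50 gives effectively independent states and the F-test p-values behave
  # binomially at both thresholds; raw states are used because the l1
  # shared denominator adds a small measured variance inflation (vignette)
  ps <- numeric(0)
  for (rep in 1:40) {
    m <- box_model(c(4, 3))
    s1 <- sample_fluxes(m, 150, seed = 100 + rep, thinning = 50, burnin = 300)
    s2 <- sample_fluxes(m, 150, seed = 9000 + rep, thinning = 50, burnin = 300)
    d <- call_altered_reactions(s1, s2)
    ps <- c(ps, d$table$p[grep("EX_out", d$table$reaction)])
  }
  for (alpha in c(0.05, 0.001)) {
    band <- stats::qbinom(c(0.005, 0.995), length(ps), alpha)
    hits <- sum(ps < alpha)
    expect_gte(hits, band[1])
    expect_lte(hits, band[2])
  }
})

test_that("mismatched reaction universes raise a symmetric-difference error", {
  a <- make_set(cbind(r1 = rnorm(5), r2 = rnorm(5)))
  b <- make_set(cbind(r1 = rnorm(5), r3 = rnorm(5)))
  expect_error(call_altered_reactions(a, b), "only in wt.*r2.*only in ko.*r3")
})

test_that("rollup tallies subsystems and collects affected metabolites", {
  m <- chain_model()   # R1 subsystem: Fatty acid oxidation
  tab <- data.frame(
    reaction = c("EX_A", "R1", "EX_B"),
    wt_mean = 1, ko_mean = 1, fold_change = 1, sign_change = FALSE,
    F = 0, p = 1, altered = c(FALSE, TRUE, FALSE))
  res <- structure(list(table = tab, alpha = 0.001, fc_hi = 2, fc_lo = 0.5),
                   class = "diff_flux_result")
  rl <- rollup(res, m)
  expect_equal(rl$subsystem_tally, c("Fatty acid oxidation" = 1L))
  expect_setequal(rl$affected_metabolites, c("A", "B"))
  expect_setequal(rl$lipid_metabolites, c("A", "B"))

  # non-lipid subsystem: affected nonempty, lipid empty
  tab2 <- tab
  tab2$altered <- c(TRUE, FALSE, FALSE)   # EX_A: Transport, extracellular
  res2 <- structure(list(table = tab2), class = "diff_flux_result")
  rl2 <- rollup(res2, m)
  expect_setequal(rl2$affected_metabolites, "A")
  expect_length(rl2$lipid_metabolites, 0)

  # shared metabolites counted once; tallies sum to altered count
  tab3 <- tab
  tab3$altered <- c(FALSE, TRUE, TRUE)
  res3 <- structure(list(table = tab3), class = "diff_flux_result")
  rl3 <- rollup(res3, m)
  expect_equal(sum(rl3$subsystem_tally), rl3$n_altered)
  expect_setequal(rl3$affected_metabolites, c("A", "B"))
  expect_equal(anyDuplicated(rl3$affected_metabolites), 0)

  expect_warning(rollup(res, m, lipid_subsystems = character(0)), "empty")
})

test_that("exchange-only affected mode restricts to boundary metabolites", {
  m <- chain_model()
  tab <- data.frame(
    reaction = c("EX_A", "R1", "EX_B"),
    wt_mean = 1, ko_mean = 1, fold_change = 1, sign_change = FALSE,
    F = 0, p = 1, altered = c(FALSE, TRUE, TRUE))
  res <- structure(list(table = tab), class = "diff_flux_result")
  expect_setequal(rollup(res, m, affected_mode = "all")$affected_metabolites,
                  c("A", "B"))
  expect_setequal(rollup(res, m, affected_mode = "exchange")$affected_metabolites,
                  "B")
})
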