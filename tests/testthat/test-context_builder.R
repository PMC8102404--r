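test_that("GPR evaluation follows min/max semantics", {
  expect_equal(evaluate_gpr("g1 and g2", c(g1 = 5, g2 = 2)), 2)
  expect_equal(evaluate_gpr("g1 or g2", c(g1 = 5, g2 = 2)), 5)
  # brute-force oracle over all and/or shapes of three genes
  expr <- c(g1 = 5, g2 = 2, g3 = 4)
  expect_equal(evaluate_gpr("(g1 and g2) or g3", expr),
               max(min(5, 2), 4))
  expect_equal(evaluate_gpr("g1 and (g2 or g3)", expr),
               min(5, max(2, 4)))
  expect_equal(evaluate_gpr("(g1 or g2) and (g2 or g3)", expr),
               min(max(5, 2), max(2, 4)))
  # missing genes default to the profile median
  expect_equal(evaluate_gpr("g1 and gX", c(g1 = 5, g2 = 1, g3 = 9)), 5)
  expect_equal(evaluate_gpr("g1 and gX", c(g1 = 5, g2 = 2), missing_value = 0), 0)
})

test_that("GPR parsing reports malformed rules with a position", {
  expect_error(parse_gpr("g1 and"), "parse error")
  expect_error(parse_gpr("g1 ) g2"), "token")
  expect_error(parse_gpr("(g1 and g2"), "expected '\\)'")
  expect_error(parse_gpr("and g1"), "token 1")
  expect_null(parse_gpr(""))
})

test_that("expression constraints scale bounds by activity / threshold", {
  m <- chain_model()
  # R1 rule is "g1 and g2": activity = min
  prof <- c(g1 = 5, g2 = 5)
  # a = threshold / 2 -> bounds halved
  out <- apply_expression_constraints(m, prof, threshold = 10, floor = 0)
  expect_equal(out$reactions$upper_bound[2], 500)
  # empty-rule reactions untouched
  expect_equal(out$reactions$lower_bound[1], m$reactions$lower_bound[1])
  # a = 0, floor 0.05, bounds (-10, 10) -> (-0.5, 0.5)
  m2 <- m
  m2$reactions$lower_bound[2] <- -10
  m2$reactions$upper_bound[2] <- 10
  out2 <- apply_expression_constraints(m2, c(g1 = 0, g2 = 0),
                                       threshold = 4, floor = 0.05)
  expect_equal(out2$reactions$lower_bound[2], -0.5)
  expect_equal(out2$reactions$upper_bound[2], 0.5)
  # input model unmodified
  expect_equal(m$reactions$upper_bound[2], 1000)
  # no overlap with model genes
  expect_error(apply_expression_constraints(m, c(zz = 1)), "no genes")
})

test_that("metabolite constraints follow the secretion-positive convention", {
  m <- chain_model()
  blocked <- apply_metabolite_constraints(
    m, data.frame(metabolite_id = "A", direction = "blocked", magnitude = 0))
  expect_identical(blocked$status, "feasible")
  expect_equal(fba(blocked$model)$objective_value, 0)

  sec <- apply_metabolite_constraints(
    m, data.frame(metabolite_id = "B", direction = "secretion_min", magnitude = 2))
  expect_identical(sec$status, "feasible")
  rng <- fva(sec$model, 0)$ranges
  expect_gte(rng[rng$reaction == "EX_B", "min"], 2)

  conflict <- apply_metabolite_constraints(
    m, data.frame(metabolite_id = c("B", "B"),
                  direction = c("blocked", "secretion_min"),
                  magnitude = c(0, 2)))
  expect_identical(conflict$status, "infeasible")
  expect_true(length(conflict$offending) > 0)

  expect_error(apply_metabolite_constraints(
    m, data.frame(metabolite_id = "C", direction = "blocked", magnitude = 0)),
    "no exchange")
})

test_that("knockouts close reactions and honour boolean GPR semantics", {
  m <- chain_model()
  ko_r <- knockout(m, "R1")
  expect_equal(fba(ko_r)$objective_value, 0)
  # AND dependence: gene KO of g1 closes R1
  ko_g <- knockout(m, "g1")
  j <- match("R1", ko_g$reactions$id)
  expect_equal(ko_g$reactions$lower_bound[j], 0)
  expect_equal(ko_g$reactions$upper_bound[j], 0)
  # OR redundancy keeps a reaction open
  m2 <- m
  m2$reactions$gene_reaction_rule[2] <- "(g1 and g2) or g3"
  open <- knockout(m2, "g3")
  expect_equal(open$reactions$upper_bound[2], m2$reactions$upper_bound[2])
  expect_error(knockout(m, "not_a_thing"), "unknown knockout target")
})

test_that("contextualisation is monotone and idempotent", {
  net <- make_toy_network(3, 1, 2, seed = 5)
  m <- net$model
  prof <- stats::setNames(rep(c(1, 8), length.out = length(model_genes(m))),
                          model_genes(m))
  ctx <- apply_expression_constraints(m, prof, threshold = 4, floor = 0.1)
  base_rng <- fva(m, 0)$ranges
  ctx_rng <- fva(ctx, 0)$ranges
  # feasible region never widens
  expect_true(all(ctx_rng$min >= base_rng$min - 1e-9))
  expect_true(all(ctx_rng$max <= base_rng$max + 1e-9))
  # applying the same constraints twice equals applying them once
  ctx2 <- apply_expression_constraints(ctx, prof, threshold = 4, floor = 0.1)
  expect_equal(ctx2$reactions$upper_bound, ctx$reactions$upper_bound)
  expect_equal(ctx2$reactions$lower_bound, ctx$reactions$lower_bound)
  # uniform high expression reproduces the base optimum exactly
  high <- stats::setNames(rep(100, length(model_genes(m))), model_genes(m))
  same <- apply_expression_constraints(m, high, threshold = 4)
  expect_equal(fba(same)$objective_value, fba(m)$objective_value)
})
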