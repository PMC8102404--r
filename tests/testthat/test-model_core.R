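test_that("JSON model loading round-trips and validates", {
  m <- chain_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- load_model(path, "json")
  expect_identical(m2$stoichiometry, m$stoichiometry)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_identical(m2$reactions$gene_reaction_rule, m$reactions$gene_reaction_rule)
  expect_identical(m2$objective$reaction, "EX_B")

  # undeclared metabolite in stoichiometry is a validation error
  bad <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bad$reactions[[2]]$metabolites$X <- 1
  bad_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, bad_path, auto_unbox = TRUE)
  expect_error(load_model(bad_path, "json"), "undeclared metabolite.*X")

  expect_error(load_model("no/such/file.json"), "not found")
})

test_that("SBML export matches the JSON representation", {
  m <- branched_model()
  sbml <- withr::local_tempfile(fileext = ".xml")
  write_model_sbml(m, sbml)
  m2 <- load_model(sbml, "sbml")
  expect_equal(m2$stoichiometry[rownames(m$stoichiometry), colnames(m$stoichiometry)],
               m$stoichiometry)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_identical(m2$objective$reaction, m$objective$reaction)
  # gene rules survive through fbc gene-product associations
  cm <- chain_model()
  write_model_sbml(cm, sbml)
  m3 <- load_model(sbml)
  act <- evaluate_gpr(m3$reactions$gene_reaction_rule[2], c(g1 = 5, g2 = 2))
  expect_equal(act, 2)
})

test_that("model construction enforces invariants", {
  expect_error(metabolic_model(
    data.frame(id = "A"),
    data.frame(id = "R", lower_bound = 1, upper_bound = -1),
    list(R = c(A = 1))), "lower_bound > upper_bound")
  expect_error(metabolic_model(
    data.frame(id = "A"),
    data.frame(id = "R", lower_bound = 0, upper_bound = 1),
    list(R = c(B = 1))), "undeclared")
  expect_error(metabolic_model(
    data.frame(id = "A"),
    data.frame(id = "R", lower_bound = 0, upper_bound = 1),
    list(R = c(A = 1)), objective = list(reaction = "nope")), "objective")
})

test_that("FBA solves the toy chains", {
  expect_equal(fba(chain_model())$objective_value, 10)
  # closed uptake
  closed <- chain_model()
  closed$reactions$lower_bound[1] <- 0
  expect_equal(fba(closed)$objective_value, 0)
  # two-route branched optimum 4 + 3 = 7 (hand LP)
  expect_equal(fba(branched_model())$objective_value, 7)
  # infeasible model reports status, not an exception
  inf <- chain_model()
  inf$reactions$lower_bound[3] <- 5   # force secretion with no uptake allowed
  inf$reactions$lower_bound[1] <- 0
  inf$reactions$upper_bound[1] <- 0
  res <- fba(inf)
  expect_identical(res$status, "infeasible")
  expect_true(is.na(res$objective_value))
})

test_that("FBA solution satisfies flux-vector invariants", {
  for (m in list(chain_model(), branched_model(), box_model(c(4, 3, 2)))) {
    res <- fba(m)
    expect_identical(res$status, "optimal")
    expect_true(check_flux_vector(m, res$fluxes))
  }
})

test_that("FBA optimum is invariant under reordering and reaction rescaling", {
  m <- branched_model()
  base <- fba(m)$objective_value
  # reorder reactions
  perm <- c(3, 1, 5, 2, 4)
  m2 <- metabolic_model(m$metabolites,
                        m$reactions[perm, ],
                        m$stoichiometry[, perm],
                        objective = m$objective)
  expect_equal(fba(m2)$objective_value, base)
  # scale one reaction's stoichiometry and bounds together
  m3 <- m
  m3$stoichiometry[, "R1"] <- 2 * m3$stoichiometry[, "R1"]
  j <- match("R1", m3$reactions$id)
  m3$reactions$lower_bound[j] <- m3$reactions$lower_bound[j] / 2
  m3$reactions$upper_bound[j] <- m3$reactions$upper_bound[j] / 2
  expect_equal(fba(m3)$objective_value, base)
})

test_that("FVA brackets the FBA flux and honours fraction_of_optimum", {
  m <- chain_model()
  # fully coupled chain at fraction 1: everything locked to |10|
  locked <- fva(m, 1)$ranges
  expect_equal(locked$min, c(-10, 10, 10))
  expect_equal(locked$max, c(-10, 10, 10))
  # relaxed: EX_B spans [0, 10]
  relaxed <- fva(m, 0)$ranges
  expect_equal(relaxed[relaxed$reaction == "EX_B", c("min", "max")],
               data.frame(min = 0, max = 10, row.names = 3L))
  # branched at fraction 0: route 1 spans [0, 4] (hand LP)
  br <- fva(branched_model(), 0)$ranges
  expect_equal(unlist(br[br$reaction == "R1", c("min", "max")]),
               c(min = 0, max = 4))
  # FVA min <= FBA flux <= FVA max at fraction 1
  mb <- branched_model()
  flux <- fba(mb)$fluxes
  rng <- fva(mb, 1)$ranges
  expect_true(all(rng$min <= flux[rng$reaction] + 1e-9))
  expect_true(all(flux[rng$reaction] <= rng$max + 1e-9))
})

test_that("exchange reactions are single-metabolite columns", {
  expect_setequal(exchange_reactions(chain_model()), c("EX_A", "EX_B"))
  expect_setequal(exchange_reactions(branched_model()), c("EX_A", "EX_B"))
})

test_that("the packaged example model loads and solves", {
  path <- system.file("extdata", "toy_transporter_model.json",
                      package = "fluxlip")
  m <- load_model(path)
  expect_equal(nrow(m$reactions), 12)
  expect_identical(fba(m)$status, "optimal")
})
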