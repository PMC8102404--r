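# Fixture models built in code.

# linear chain: uptake (<= cap) -> A -> B -> secretion
chain_model <- function(cap = 10) {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(
      id = c("EX_A", "R1", "EX_B"),
      lower_bound = c(-cap, 0, 0),
      upper_bound = c(0, 1000, 1000),
      subsystem = c("Transport, extracellular", "Fatty acid oxidation",
                    "Transport, extracellular"),
      gene_reaction_rule = c("", "g1 and g2", "")),
    stoichiometry = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                         EX_B = c(B = -1)),
    objective = list(reaction = "EX_B", direction = "max"),
    id = "chain")
}

# two routes A->B: direct (cap 4) and via C (cap 3); uptake <= 10
branched_model <- function() {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(
      id = c("EX_A", "R1", "R2a", "R2b", "EX_B"),
      lower_bound = c(-10, 0, 0, 0, 0),
      upper_bound = c(0, 4, 3, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
                         R2a = c(A = -1, C = 1), R2b = c(C = -1, B = 1),
                         EX_B = c(B = -1)),
    objective = list(reaction = "EX_B", direction = "max"),
    id = "branched")
}

# n independent "box" reactions: uptake_i -> A_i -> secretion_i, conversion
# bounded by cap_i; the flux polytope is an axis-aligned box over conversions
box_model <- function(caps = c(4, 3)) {
  n <- length(caps)
  mets <- data.frame(id = paste0("A", seq_len(n)))
  rxns <- NULL
  stoich <- list()
  for (i in seq_len(n)) {
    rxns <- rbind(rxns, data.frame(
      id = c(paste0("EX_in_", i), paste0("EX_out_", i)),
      lower_bound = c(-caps[i], 0), upper_bound = c(0, caps[i])))
    stoich[[paste0("EX_in_", i)]] <- stats::setNames(-1, paste0("A", i))
    stoich[[paste0("EX_out_", i)]] <- stats::setNames(-1, paste0("A", i))
  }
  metabolic_model(mets, rxns, stoich,
                  objective = list(reaction = "EX_out_1", direction = "max"),
                  id = "box")
}
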