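# Synthetic inputs with known ground truth for every analysis stage.
#
# The generated world mirrors the table shapes of a transporter-knockout
# serum study: a toy metabolic network whose knockout closes a basolateral
# uptake exchange (the transporter's role), a metabolomics table of ~342
# lipids over ~37 subpathways with 5 samples per group, and a structure set
# of 86 elevated (acyclic carboxylic chains) vs 40 decreased
# (polycyclic / charged species) lipids.

LIPID_SUBSYSTEM_VOCAB <- c(
  "Fatty acid oxidation", "Bile acid synthesis", "Sphingolipid metabolism",
  "Eicosanoid metabolism", "Glycerophospholipid metabolism",
  "Cholesterol metabolism")
NONLIPID_SUBSYSTEM_VOCAB <- c(
  "Glycolysis/gluconeogenesis", "Citric acid cycle", "Amino acid metabolism",
  "Nucleotide interconversion", "Pentose phosphate pathway",
  "Vitamin metabolism")

#' Generate a toy metabolic network with a deletable uptake exchange
#'
#' Builds `n_pathways` parallel linear pathways (uptake exchange ->
#' conversion(s) -> secretion exchange) sharing a recycled cofactor.
#' `branch_count` pathways get a second, capacity-limited route. One
#' pathway's uptake exchange is the designated knockout target (the
#' transporter analogue). Ground truth is the exact set of reactions whose
#' feasible flux range changes under the knockout, from FVA on both models.
#'
#' @param n_pathways number of parallel pathways (>= 2).
#' @param branch_count how many pathways get an alternative branch.
#' @param ko_pathway index of the pathway whose uptake is knocked out.
#' @param seed integer seed (subsystem assignment).
#' @param uptake_bound max uptake flux per pathway (default 10).
#' @return list with `model` (a `metabolic_model`), `ko_reaction`,
#'   `ko_gene`, `ko_model` (knockout applied), `ground_truth` (reaction ids
#'   whose FVA range changes), `lipid_pathways` (indices labelled with lipid
#'   subsystems).
#' @export
make_toy_network <- function(n_pathways = 3, branch_count = 1,
                             ko_pathway = 2, seed = 1,
                             uptake_bound = 10) {
  if (n_pathways < 2) stop("need at least 2 pathways")
  if (ko_pathway > n_pathways) {
    stop("ko_pathway ", ko_pathway, " exceeds n_pathways ", n_pathways)
  }
  branch_count <- min(branch_count, n_pathways)
  rng <- local_rng(seed)
  lipid_idx <- sort(rng$sample(seq_len(n_pathways),
                               ceiling(n_pathways / 2)))
  mets <- data.frame(id = c("cof_ox", "cof_red"),
                     name = c("cofactor (oxidised)", "cofactor (reduced)"),
                     compartment = "c", hmdb_id = "",
                     stringsAsFactors = FALSE)
  rxns <- NULL
  stoich <- list()
  subsys_pick <- function(i) {
    vocab <- if (i %in% lipid_idx) LIPID_SUBSYSTEM_VOCAB else NONLIPID_SUBSYSTEM_VOCAB
    vocab[(i - 1) %% length(vocab) + 1]
  }
  for (i in seq_len(n_pathways)) {
    A <- sprintf("A%d", i); B <- sprintf("B%d", i)
    mets <- rbind(mets, data.frame(
      id = c(A, B), name = c(A, B), compartment = "c",
      hmdb_id = c("", sprintf("HMDB%05d", 100 + i)),
      stringsAsFactors = FALSE))
    sub <- subsys_pick(i)
    rxns <- rbind(rxns, data.frame(
      id = c(sprintf("EX_upt_%d", i), sprintf("CONV_%d", i),
             sprintf("EX_sec_%d", i)),
      name = c(sprintf("uptake exchange, pathway %d", i),
               sprintf("conversion, pathway %d", i),
               sprintf("secretion exchange, pathway %d", i)),
      lower_bound = c(-uptake_bound, 0, 0),
      upper_bound = c(0, uptake_bound, uptake_bound),
      subsystem = c("Transport, extracellular", sub,
                    "Transport, extracellular"),
      gene_reaction_rule = c("", sprintf("(g%da and g%db) or g%dc", i, i, i), ""),
      stringsAsFactors = FALSE))
    stoich[[sprintf("EX_upt_%d", i)]] <- stats::setNames(-1, A)
    stoich[[sprintf("CONV_%d", i)]] <- stats::setNames(
      c(-1, 1, -1, 1), c(A, B, "cof_ox", "cof_red"))
    stoich[[sprintf("EX_sec_%d", i)]] <- stats::setNames(-1, B)
    if (i <= branch_count) {
      C <- sprintf("C%d", i)
      mets <- rbind(mets, data.frame(id = C, name = C, compartment = "c",
                                     hmdb_id = "", stringsAsFactors = FALSE))
      rxns <- rbind(rxns, data.frame(
        id = c(sprintf("BR1_%d", i), sprintf("BR2_%d", i)),
        name = c(sprintf("branch step 1, pathway %d", i),
                 sprintf("branch step 2, pathway %d", i)),
        lower_bound = 0, upper_bound = uptake_bound / 2,
        subsystem = subsys_pick(i),
        gene_reaction_rule = sprintf("g%dd", i),
        stringsAsFactors = FALSE))
      stoich[[sprintf("BR1_%d", i)]] <- stats::setNames(c(-1, 1), c(A, C))
      stoich[[sprintf("BR2_%d", i)]] <- stats::setNames(c(-1, 1), c(C, B))
    }
  }
  rxns <- rbind(rxns, data.frame(
    id = "COF_REGEN", name = "cofactor regeneration",
    lower_bound = 0, upper_bound = 1000,
    subsystem = "Miscellaneous", gene_reaction_rule = "",
    stringsAsFactors = FALSE))
  stoich[["COF_REGEN"]] <- c(cof_red = -1, cof_ox = 1)
  model <- metabolic_model(
    mets, rxns, stoich,
    objective = list(reaction = "EX_sec_1", direction = "max"),
    id = sprintf("toy_%dpath_seed%d", n_pathways, seed))

  ko_reaction <- sprintf("EX_upt_%d", ko_pathway)
  ko_model <- knockout(model, ko_reaction)
  base_fva <- fva(model, fraction_of_optimum = 0)
  ko_fva <- fva(ko_model, fraction_of_optimum = 0)
  if (base_fva$status != "optimal" || ko_fva$status != "optimal") {
    stop("toy network unexpectedly infeasible")
  }
  changed <- abs(base_fva$ranges$min - ko_fva$ranges$min) > 1e-9 |
    abs(base_fva$ranges$max - ko_fva$ranges$max) > 1e-9
  list(model = model, ko_model = ko_model,
       ko_reaction = ko_reaction,
       ko_gene = sprintf("g%da", ko_pathway),
       ground_truth = base_fva$ranges$reaction[changed],
       lipid_pathways = lipid_idx)
}

#' Generate a metabolomics table with planted group effects
#'
#' Log-normal abundances per metabolite; a planted fraction receives a
#' multiplicative effect in the case group (half elevated at `effect_fold`,
#' half decreased at `1/effect_fold`). Metabolites are assigned to
#' subpathways of sizes 3-30 contiguously, so planted effects concentrate in
#' the early subpathways (giving truly enriched pathways). Cells go missing
#' completely at random at `missing_rate`.
#'
#' @param n_metabolites number of metabolites (default 342).
#' @param n_per_group samples per group (default 5).
#' @param planted_fraction fraction of metabolites with a real effect
#'   (default 0.35, mirroring the observed altered fraction in this kind of
#'   serum panel).
#' @param effect_fold multiplicative group effect (default 4).
#' @param sigma log-scale noise SD (default 0.3).
#' @param missing_rate MCAR missing probability in `[0, 0.5]` (default 0.05).
#' @param groups two group labels, control first (default `c("WT", "KO")`).
#' @param seed integer seed.
#' @return list with `table` (a `metabolite_table`), `ground_truth`
#'   (data.frame `metabolite_id`, `direction`).
#' @export
make_metabolomics <- function(n_metabolites = 342, n_per_group = 5,
                              planted_fraction = 0.35, effect_fold = 4,
                              sigma = 0.3, missing_rate = 0.05,
                              groups = c("WT", "KO"), seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate <= 0.5, effect_fold > 0,
            n_metabolites > 0, n_per_group > 1)
  rng <- local_rng(seed)
  ids <- sprintf("met_%03d", seq_len(n_metabolites))
  n_planted <- round(planted_fraction * n_metabolites)
  n_up <- ceiling(n_planted / 2)
  direction <- rep("none", n_metabolites)
  direction[seq_len(n_up)] <- "elevated"
  if (n_planted > n_up) direction[(n_up + 1):n_planted] <- "decreased"

  # contiguous subpathway blocks of size 3-30 (planted effects concentrate
  # in the early blocks by construction)
  sizes <- integer(0)
  while (sum(sizes) < n_metabolites) {
    sizes <- c(sizes, rng$sample(3:30, 1))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_metabolites)
  if (sizes[length(sizes)] < 1) sizes <- sizes[-length(sizes)]
  sizes[length(sizes)] <- n_metabolites - sum(sizes[-length(sizes)])
  subpathway <- rep(sprintf("Subpathway %02d", seq_along(sizes)), sizes)

  samples <- c(paste0(groups[1], "_", seq_len(n_per_group)),
               paste0(groups[2], "_", seq_len(n_per_group)))
  grp <- stats::setNames(rep(groups, each = n_per_group), samples)
  base <- rng$runif(n_metabolites, 2, 6)  # log-scale baselines
  ab <- matrix(NA_real_, length(samples), n_metabolites,
               dimnames = list(samples, ids))
  for (j in seq_len(n_metabolites)) {
    mult <- switch(direction[j], elevated = effect_fold,
                   decreased = 1 / effect_fold, 1)
    mu <- rep(base[j], length(samples))
    mu[grp == groups[2]] <- mu[grp == groups[2]] + log(mult)
    ab[, j] <- exp(mu + sigma * rng$rnorm(length(samples)))
  }
  if (missing_rate > 0) {
    miss <- rng$runif(length(ab)) < missing_rate
    ab[miss] <- NA_real_
  }
  annotations <- data.frame(
    metabolite_id = ids, superpathway = "Lipid", subpathway = subpathway,
    hmdb_id = sprintf("HMDB%05d", 10000 + seq_len(n_metabolites)),
    stringsAsFactors = FALSE)
  tab <- metabolite_table(ab, grp, annotations)
  list(table = tab,
       ground_truth = data.frame(
         metabolite_id = ids[direction != "none"],
         direction = direction[direction != "none"],
         stringsAsFactors = FALSE))
}

# polycyclic scaffolds for the decreased class (2-4 fused saturated rings)
POLYCYCLIC_TEMPLATES <- c(
  decalin = "C1CCC2CCCCC2C1",
  perhydrophenanthrene = "C1CCC2C(C1)CCC1CCCCC21",
  sterane = "C1CCC2C(C1)CCC1C2CCC2CCCC12"
)
CHARGED_HEADS <- c("CC[NH3+]", "C[N+](C)(C)C", "CCNC(=O)C[NH3+]")
NEUTRAL_DECOR <- c("O", "CO", "CCO", "C(C)O")

#' Generate a two-class synthetic lipid structure set
#'
#' The elevated class is acyclic mono-/di-carboxylic chains with hydroxyl
#' and double-bond decorations (no ring tokens in the grammar, so
#' `nof_Rings = 0` by construction). The decreased class is built from
#' polycyclic saturated scaffolds (2-4 fused rings) decorated with hydroxyls
#' or positively charged head groups, so `nof_Rings >= 2` and
#' positive-charge density are high by construction. Deterministic under
#' `seed`.
#'
#' @param n_elevated,n_decreased class sizes (defaults 86 and 40, the
#'   shape of the serum-lipid comparison this emulates).
#' @param chain_range inclusive carbon-count range for elevated chains
#'   (default 12:24).
#' @param seed integer seed.
#' @return a `molecule_records` object with ground-truth `direction` labels.
#' @export
make_lipid_classes <- function(n_elevated = 86, n_decreased = 40,
                               chain_range = 12:24, seed = 1) {
  if (n_elevated < 1 || n_decreased < 1) stop("class sizes must be >= 1")
  rng <- local_rng(seed)
  elev_sub <- c("Long Chain Fatty Acid", "Polyunsaturated Fatty Acid",
                "Fatty Acid, Dicarboxylate", "Fatty Acid, Monohydroxy")
  decr_sub <- c("Primary Bile Acid Metabolism",
                "Secondary Bile Acid Metabolism", "Ceramides",
                "Sphingolipid Metabolism")
  recs <- NULL
  for (i in seq_len(n_elevated)) {
    len <- rng$sample(chain_range, 1)
    n_db <- rng$sample(0:3, 1)          # cis double bonds
    n_oh <- rng$sample(0:2, 1)          # mid-chain hydroxyls
    diacid <- rng$runif(1) < 0.2
    # assemble the chain body: (len - 1) carbons before the acid carbon
    body <- rep("C", len - 1)
    if (n_db > 0) {
      spots <- rng$sample(seq(2, len - 3, by = 2), min(n_db, (len - 4) %/% 2))
      for (s in spots) body[s] <- "C=C"   # consumes the next position
      body[spots + 1] <- ""
    }
    if (n_oh > 0) {
      free <- which(body == "C")
      free <- free[free > 1 & free < len - 2]
      if (length(free)) {
        spots <- rng$sample(free, min(n_oh, length(free)))
        body[spots] <- "C(O)"
      }
    }
    head <- if (diacid) "OC(=O)" else ""
    smiles <- paste0(head, paste(body, collapse = ""), "C(=O)O")
    recs <- rbind(recs, data.frame(
      name = sprintf("elev_%03d", i), smiles = smiles,
      direction = "elevated",
      subpathway = elev_sub[(i - 1) %% length(elev_sub) + 1],
      stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_decreased)) {
    core <- POLYCYCLIC_TEMPLATES[[rng$sample(length(POLYCYCLIC_TEMPLATES), 1)]]
    charged <- rng$runif(1) < 0.6
    decor <- if (charged) {
      CHARGED_HEADS[[rng$sample(length(CHARGED_HEADS), 1)]]
    } else {
      NEUTRAL_DECOR[[rng$sample(length(NEUTRAL_DECOR), 1)]]
    }
    extra <- if (rng$runif(1) < 0.5) "C(O)" else ""
    smiles <- paste0(core, extra, decor)
    recs <- rbind(recs, data.frame(
      name = sprintf("decr_%03d", i), smiles = smiles,
      direction = "decreased",
      subpathway = decr_sub[(i - 1) %% length(decr_sub) + 1],
      stringsAsFactors = FALSE))
  }
  molecule_records(recs)
}
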