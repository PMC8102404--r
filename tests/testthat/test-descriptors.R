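# Expected counts below were frozen from an independent cheminformatics
# toolkit (ring counts, rotatable bonds, stereocenters, sp3 carbons,
# acyclic carbons, molecular weight, H-bond donors) on the same SMILES.
# Known deviation: purely symmetric ring-fusion stereocenters (e.g. decalin)
# are not counted by the symmetry-class approximation used here.

ORACLE <- list(
  pentadecanoic = list(
    smiles = "CCCCCCCCCCCCCCC(=O)O",
    rings = 0, cooh = 1, oh = 0, rotb = 13, chirals = 0, csp3 = 14,
    cr0 = 15, mw = 242.40, hbd = 1),
  benzene = list(
    smiles = "c1ccccc1",
    rings = 1, cooh = 0, oh = 0, rotb = 0, chirals = 0, csp3 = 0,
    cr0 = 0, mw = 78.11, hbd = 0),
  taurocholate = list(
    smiles = paste0("C[C@H](CCC(=O)NCCS(=O)(=O)O)[C@H]1CC[C@@H]2[C@@]1([C@H]",
                    "(C[C@H]3[C@H]2[C@@H](C[C@H]4[C@@]3(CC[C@H](C4)O)C)O)O)C"),
    rings = 4, cooh = 0, rotb = 7, chirals = 11, csp3 = 25, cr0 = 9,
    mw = 515.71, hbd = 5),
  palmitoleic = list(
    smiles = "CCCCCC/C=C\\CCCCCCCC(=O)O",
    rings = 0, cooh = 1, oh = 0, rotb = 13, chirals = 0, csp3 = 13,
    cr0 = 16, mw = 254.41, hbd = 1),
  prostaglandin_e2 = list(
    smiles = paste0("CCCCC[C@@H](O)/C=C/[C@H]1[C@H](O)CC(=O)[C@@H]1C/",
                    "C=C\\CCCC(=O)O"),
    rings = 1, cooh = 1, oh = 2, rotb = 12, chirals = 4, csp3 = 14,
    cr0 = 15, mw = 352.47, hbd = 3),
  cholate = list(
    smiles = paste0("C[C@H](CCC(=O)O)[C@H]1CC[C@@H]2[C@@]1([C@H](C[C@H]3",
                    "[C@H]2[C@@H](C[C@H]4[C@@]3(CC[C@H](C4)O)C)O)O)C"),
    rings = 4, cooh = 1, oh = 3, rotb = 4, chirals = 11, csp3 = 23,
    cr0 = 7, mw = 408.58, hbd = 4),
  glutarate = list(
    smiles = "OC(=O)CCCC(=O)O",
    rings = 0, cooh = 2, oh = 0, rotb = 4, chirals = 0, csp3 = 3,
    cr0 = 5, mw = 132.12, hbd = 2),
  choline_frag = list(
    smiles = "C[N+](C)(C)CCO",
    rings = 0, cooh = 0, oh = 1, rotb = 2, chirals = 0, csp3 = 5,
    cr0 = 5, mw = 104.17, hbd = 1)
)

test_that("named descriptors match the frozen oracle values", {
  for (nm in names(ORACLE)) {
    o <- ORACLE[[nm]]
    d <- compute_descriptors(o$smiles, nm)
    expect_equal(unname(d["nof_Rings"]), o$rings, label = paste(nm, "rings"))
    expect_equal(unname(d["nof_COOH"]), o$cooh, label = paste(nm, "cooh"))
    if (!is.null(o$oh)) {
      expect_equal(unname(d["nof_OH"]), o$oh, label = paste(nm, "oh"))
    }
    expect_equal(unname(d["nof_RotB"]), o$rotb, label = paste(nm, "rotb"))
    expect_equal(unname(d["nof_Chirals"]), o$chirals, label = paste(nm, "chirals"))
    expect_equal(unname(d["C_sp3"]), o$csp3, label = paste(nm, "csp3"))
    expect_equal(unname(d["C_R0"]), o$cr0, label = paste(nm, "cr0"))
    expect_equal(unname(d["mol_weight"]), o$mw, tolerance = 1e-3,
                 label = paste(nm, "mw"))
    expect_equal(unname(d["hbd"]), o$hbd, label = paste(nm, "hbd"))
  }
})

test_that("amide bonds are excluded from rotatable-bond counts", {
  amide <- compute_descriptors("CCC(=O)NCC")   # one amide C-N inside
  ester <- compute_descriptors("CCC(=O)OCC")
  expect_equal(unname(amide["nof_RotB"]), 2)   # CC-C and N-CC only
  expect_equal(unname(ester["nof_RotB"]), 3)   # ester C-O rotates
})

test_that("count descriptors satisfy the partition invariants", {
  smis <- c("CCCCCCCCCCCCCCC(=O)O", "c1ccccc1CCO", "C1CCC2CCCCC2C1CC(=O)O",
            "C[C@H](O)CC(=O)[O-]", "C[N+](C)(C)CC(O)CC(=O)O")
  for (s in smis) {
    d <- compute_descriptors(s)
    counts <- d[c("nof_Rings", "nof_COOH", "nof_OH", "nof_RotB",
                  "nof_Chirals", "C_sp3", "C_R0")]
    expect_true(all(counts >= 0))
    expect_true(all(counts == round(counts)))
    # sp3 + sp2/aromatic carbons partition the carbons (no sp carbons here)
    expect_equal(unname(d["C_sp3"] + d["C_sp2"]), unname(d["n_carbons"]),
                 info = s)
    expect_lte(d["C_R0"], d["n_carbons"])
    expect_lte(d["ring_atoms"], d["heavy_atoms"])
  }
})

test_that("descriptors are deterministic and complete", {
  a <- compute_descriptors("CC(C)CC(=O)O")
  b <- compute_descriptors("CC(C)CC(=O)O")
  expect_identical(a, b)
  expect_false(anyNA(a))
  expect_gte(length(a), 30)   # the panel is ~33 features
})

test_that("partial charges are physically signed", {
  d <- compute_descriptors("C[N+](C)(C)C")      # quaternary ammonium
  expect_gt(d["posCharge_sum"], 0.5)
  d2 <- compute_descriptors("CC(=O)[O-]")       # carboxylate
  expect_gt(d2["negCharge_sum"], 0.5)
  # neutral alkane carries almost no positive charge per volume
  d3 <- compute_descriptors("CCCCCCCC")
  expect_lt(d3["posCharge_per_volume"], d["posCharge_per_volume"])
})

test_that("unparseable SMILES name the offending record", {
  expect_error(compute_descriptors("C(((", name = "bad_lipid"), "bad_lipid")
})
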