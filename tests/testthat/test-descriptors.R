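# Descriptor engine: named examples, masking contracts, and invariance to
# atom-index permutation. The exhaustive oracle-equivalence sweep lives in
# test-acceptance.R.

mols <- test_molecules()
graphs <- lapply(mols, heavy_graph)

test_that("simple properties match hand counts", {
  p_eth <- simple_properties(mols[["ethanol"]])
  expect_equal(unname(p_eth[c("nHeavy", "nRings", "nHBD", "nHBA")]),
               c(3, 0, 1, 1))
  expect_equal(unname(simple_properties(mols[["benzene"]])["nRings"]), 1)
  naph <- standardize(read_smiles("c1ccc2ccccc2c1", "naphthalene")[[1]])
  expect_equal(unname(simple_properties(naph)["nRings"]), 2)  # 11 - 10 + 1
  expect_equal(unname(simple_properties(mols[["benzene"]])["MW"]),
               6 * 12 + 6 * 1.0078250319, tolerance = 1e-6)
  # rotatable bonds: butane has exactly one (central C-C)
  expect_equal(unname(simple_properties(mols[["butane"]])["nRotB"]), 1)
})

test_that("Wiener index matches brute-force shortest paths", {
  expect_equal(wiener_index(graphs[["propane"]]), 4)
  expect_equal(wiener_index(graphs[["cyclobutane"]]), 8)
  m <- read_smiles("C", "methane")[[1]]
  expect_equal(wiener_index(heavy_graph(m)), 0)
})

test_that("centric index follows the pruning rule", {
  expect_equal(centric_index(graphs[["propane"]]), 5)    # 2^2 + 1
  expect_equal(centric_index(graphs[["butane"]]), 8)     # 2^2 + 2^2
  m <- read_smiles("C", "methane")[[1]]
  expect_equal(centric_index(heavy_graph(m)), 1)         # lone vertex
})

test_that("chi indices reproduce closed-form cases", {
  expect_equal(unname(chi_indices(heavy_graph(
    read_smiles("CC", "ethane")[[1]]))["Xp.1"]), 1.0)
  expect_equal(unname(chi_indices(graphs[["cyclopentane"]])["Xch.5"]),
               1 / sqrt(32), tolerance = 1e-12)
  expect_equal(unname(chi_indices(graphs[["isobutane"]])["Xc.3"]),
               1 / sqrt(3), tolerance = 1e-12)
})

test_that("kappa indices use path counts and mask degenerate orders", {
  k <- kappa_indices(graphs[["propane"]])
  expect_equal(unname(k["kappa1"]), 3.0)
  expect_equal(unname(k["kappa2"]), 2.0)
  k2 <- kappa_indices(heavy_graph(read_smiles("CC", "ethane")[[1]]))
  expect_true(is.na(k2["kappa2"]))
})

test_that("E-state: intrinsic states, S(27) sum and the zero-sum perturbation", {
  es <- estate_indices(heavy_graph(read_smiles("CC", "ethane")[[1]]))
  expect_equal(unname(es["SsCH3"]), 4.0)   # two carbons with I = 2, dI = 0
  g <- graphs[["benzene"]]
  es_b <- estate_indices(g)
  # six equivalent aromatic CH atoms: dI = 0, S = I
  I_ar <- ((2 / 2)^2 * 3 + 1) / 2
  expect_equal(unname(es_b["SaaCH"]), 6 * I_ar, tolerance = 1e-12)
  # sum of perturbations vanishes: total S equals total I
  for (nm in c("mea", "isopentane", "pyridine", "toluene")) {
    gg <- graphs[[nm]]
    N <- c(C = 2, N = 2, O = 2)[gg$element]
    I <- ((2 / N)^2 * gg$deltav + 1) / pmax(gg$degree, 1)
    expect_equal(unname(estate_indices(gg)["SsumS"]), sum(I),
                 tolerance = 1e-12 * gg$n)
  }
})

test_that("rugosity behaves like a folding measure", {
  one <- embed_coordinates(read_smiles("C", "methane")[[1]])
  expect_equal(rugosity(one), 1.0, tolerance = 0.05)
  lin <- embed_coordinates(mols[["hexane"]])
  cyc <- embed_coordinates(mols[["cyclohexane"]])
  expect_gte(rugosity(lin), rugosity(cyc))
  # dimensionless: scaling coordinates and radii leaves the ratio unchanged
  xyz <- as.matrix(lin$atoms[, c("x", "y", "z")])
  r <- rep(1.7, nrow(xyz))
  expect_equal(rugosity(xyz, radii = r, probe = 1.4),
               rugosity(2 * xyz, radii = 2 * r, probe = 2.8, spacing = 0.8),
               tolerance = 0.05)
})

test_that("compute_all fills or masks every registry entry", {
  reg <- descriptor_registry()
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true(all(c("Rugty", "Tcent", "SaaCH", "Xch.5") %in% reg$name))
  v <- compute_all(mols[["benzene"]], reg)
  expect_length(v, nrow(reg))
  expect_false(anyNA(v[!reg$requires_3d]))
  expect_true(all(is.na(v[reg$requires_3d])))       # no coordinates yet
  v3 <- compute_all(embed_coordinates(mols[["benzene"]]), reg)
  expect_false(anyNA(v3))
  # determinism
  expect_identical(v3, compute_all(embed_coordinates(mols[["benzene"]]), reg))
})

test_that("descriptors are invariant to atom-index permutation", {
  reg <- descriptor_registry()
  for (nm in c("isopentane", "methylcyclopentane", "pyridine", "mea")) {
    m <- mols[[nm]]
    n <- nrow(m$atoms)
    set.seed(42)
    perm <- sample(n)
    inv <- match(seq_len(n), perm)
    at <- m$atoms[perm, , drop = FALSE]; rownames(at) <- NULL
    bd <- m$bonds
    bd$a1 <- inv[bd$a1]; bd$a2 <- inv[bd$a2]
    m2 <- molecule(m$id, at, bd)
    v1 <- compute_all(m, reg); v2 <- compute_all(m2, reg)
    expect_equal(v1[!reg$requires_3d], v2[!reg$requires_3d], tolerance = 1e-10)
  }
})

test_that("descriptor tables round-trip through CSV with masked cells", {
  tab <- suppressWarnings(compute_descriptors(mols[c("propane", "benzene")]))
  path <- tempfile(fileext = ".csv")
  write_descriptor_table(tab, path)
  back <- read_descriptor_table(path)
  expect_equal(names(back), names(tab))
  expect_equal(back$Xp.1, tab$Xp.1, tolerance = 1e-12)
  expect_true(all(is.na(back$Rugty)))
})
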