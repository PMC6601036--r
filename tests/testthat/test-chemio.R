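# Molecule parsing, standardization and the heavy-atom graph view.

test_that("SMILES parsing fills hydrogen counts and perceives aromaticity", {
  ms <- read_smiles(c("CCO", "c1ccccc1", "C1CCCC1"),
                    ids = c("ethanol", "benzene", "cyclopentane"))
  expect_length(ms, 3L)
  eth <- ms[[1]]
  expect_equal(nrow(eth$atoms), 3L)
  expect_equal(nrow(eth$bonds), 2L)
  expect_equal(eth$atoms$nH, c(3L, 2L, 1L))
  bz <- ms[[2]]
  expect_equal(sum(bz$atoms$aromatic), 6L)
  expect_equal(sum(bz$bonds$aromatic), 6L)
  cp <- ms[[3]]
  expect_equal(nrow(cp$atoms), 5L)
  expect_equal(nrow(cp$bonds), 5L)
  expect_false(any(cp$atoms$aromatic))
})

test_that("invalid SMILES are rejected whole, with a diagnostic", {
  expect_warning(ms <- read_smiles(c("CCO", "C1CC"), c("ok", "broken")),
                 "rejected")
  expect_length(ms, 1L)
  fails <- attr(ms, "failures")
  expect_equal(fails$id, "broken")
})

test_that("standardize strips salts, neutralizes protonation charges, and is idempotent", {
  m <- read_smiles("CC(=O)[O-].[Na+]", "sodium_acetate")[[1]]
  s <- standardize(m)
  expect_equal(nrow(s$atoms), 4L)           # acetic acid fragment
  expect_true(all(s$atoms$charge == 0L))
  expect_equal(sum(s$atoms$element == "O" & s$atoms$nH == 1L), 1L)
  expect_identical(standardize(s), s)
  bz <- standardize(read_smiles("c1ccccc1", "benzene")[[1]])
  expect_identical(standardize(bz), bz)
  # quaternary ammonium cannot be fixed by deprotonation: left intact
  q <- standardize(read_smiles("C[N+](C)(C)C.[Cl-]", "tmab")[[1]])
  expect_equal(sum(q$atoms$charge), 1L)
})

test_that("equal-size fragment tie is broken deterministically", {
  m <- read_smiles("CCO.CCN", "mix")[[1]]
  s1 <- standardize(m)
  s2 <- standardize(read_smiles("CCN.CCO", "mix")[[1]])
  # same winner regardless of input fragment order
  expect_setequal(s1$atoms$element, s2$atoms$element)
})

test_that("heavy graph degrees follow the Kier-Hall convention", {
  eth <- heavy_graph(read_smiles("CC", "ethane")[[1]])
  expect_equal(eth$degree, c(1L, 1L))
  expect_equal(eth$deltav, c(1, 1))
  etoh <- heavy_graph(read_smiles("CCO", "ethanol")[[1]])
  expect_equal(etoh$deltav[etoh$element == "O"], 5)
  py <- heavy_graph(standardize(read_smiles("c1ccncc1", "pyridine")[[1]]))
  expect_equal(py$degree[py$element == "N"], 2L)
  expect_equal(py$deltav[py$element == "N"], 5)
})

test_that("out-of-subset elements fail loudly in heavy_graph", {
  m <- read_smiles("CC(=O)[O-].[Na+]", "salt")[[1]]   # Na still present
  expect_error(heavy_graph(m), "unsupported element")
})

test_that("degree sum equals twice the edge count", {
  for (m in test_molecules()) {
    g <- heavy_graph(m)
    expect_equal(sum(g$degree), 2L * nrow(g$edges))
  }
})

test_that("SDF round-trip preserves atoms, bonds and coordinates", {
  mols <- lapply(test_molecules()[c("propane", "benzene", "methylcyclopentane")],
                 embed_coordinates)
  path <- tempfile(fileext = ".sdf")
  write_sdf(mols, path)
  back <- read_sdf(path)
  expect_length(back, 3L)
  for (i in seq_along(mols)) {
    expect_equal(nrow(back[[i]]$atoms), nrow(mols[[i]]$atoms))
    expect_equal(nrow(back[[i]]$bonds), nrow(mols[[i]]$bonds))
    expect_lt(max(abs(back[[i]]$atoms$x - mols[[i]]$atoms$x)), 1e-4)
    expect_lt(max(abs(back[[i]]$atoms$z - mols[[i]]$atoms$z)), 1e-4)
  }
})

test_that("read_sdf skips malformed records and keeps order", {
  good <- write_sdf(
    lapply(test_molecules()[c("propane", "ethanol")], embed_coordinates),
    tempfile(fileext = ".sdf"))
  lines <- readLines(good)
  # corrupt the middle: insert a record with a broken counts line
  bad_rec <- c("broken", "  comment", "", "  x  y bogus", "M  END", "$$$$")
  first_end <- which(lines == "$$$$")[1]
  mixed <- c(lines[1:first_end], bad_rec, lines[(first_end + 1):length(lines)])
  path <- tempfile(fileext = ".sdf")
  writeLines(mixed, path)
  expect_warning(ms <- read_sdf(path), "skipped")
  expect_length(ms, 2L)
  expect_equal(ms[[1]]$id, "propane")
  expect_equal(ms[[2]]$id, "ethanol")
  expect_equal(nrow(attr(ms, "failures")), 1L)
})

test_that("empty SDF yields an empty sequence", {
  path <- tempfile(fileext = ".sdf")
  writeLines(character(), path)
  expect_length(read_sdf(path), 0L)
})

test_that("3D embedding is deterministic and marks coordinates present", {
  m <- test_molecules()[["hexane"]]
  expect_false(has_coordinates(m))
  e1 <- embed_coordinates(m); e2 <- embed_coordinates(m)
  expect_true(has_coordinates(e1))
  expect_identical(e1$atoms, e2$atoms)
  # embedding respects bonded distances roughly (MDS of the path graph)
  d12 <- sqrt(sum((e1$atoms[1, c("x", "y", "z")] - e1$atoms[2, c("x", "y", "z")])^2))
  expect_gt(d12, 0.5)
})

test_that("M CHG lines supersede atom-line charge codes", {
  m <- embed_coordinates(standardize(read_smiles("CCO", "x")[[1]]))
  path <- tempfile(fileext = ".sdf")
  lines <- readLines(write_sdf(m, path))
  lines <- append(lines, "M  CHG  1   3  -1", after = which(lines == "M  END") - 1L)
  writeLines(lines, path)
  back <- read_sdf(path)[[1]]
  expect_equal(back$atoms$charge[3], -1L)
})
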