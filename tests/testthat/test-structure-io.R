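test_that("PDB round trip preserves atoms, names and coordinates", {
  toy <- makeToyEnzyme(seed = 3)
  f <- tempfile(fileext = ".pdb")
  writeStructure(toy$structure, f)
  s2 <- readStructure(f)
  a1 <- atoms(toy$structure); a2 <- atoms(s2)
  expect_equal(nrow(a2), toy$manifest$nAtoms)
  expect_equal(a2$name, a1$name)
  expect_equal(a2$resname, a1$resname)
  expect_equal(a2$resno, a1$resno)
  expect_equal(a2$het, a1$het)
  expect_equal(round(a2$x, 3), round(a1$x, 3))
  expect_equal(round(a2$y, 3), round(a1$y, 3))
  expect_equal(round(a2$z, 3), round(a1$z, 3))
  ## second round trip is exact against the first re-read
  f2 <- tempfile(fileext = ".pdb")
  writeStructure(s2, f2)
  expect_equal(atoms(readStructure(f2)), a2)
})

test_that("unreadable and atom-free files raise structured errors", {
  expect_error(readStructure(tempfile()), class = "catalocavity_io_error")
  f <- tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(readStructure(f), class = "catalocavity_format_error")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(readStructure(f), class = "catalocavity_format_error")
})

test_that("a single HETATM flavin record parses as one hetero atom", {
  f <- tempfile(fileext = ".pdb")
  writeLines(pdbLine("HETATM", 1, "N5", " ", "FAD", "A", 600,
                     -2.5, 1.4, 0, elem = "N"), f)
  s <- readStructure(f)
  expect_equal(nAtoms(s), 1L)
  expect_true(atoms(s)$het)
  expect_equal(atoms(s)$name, "N5")
  expect_equal(atoms(s)$element, "N")
})

test_that("altloc resolution keeps the highest occupancy, ties to A", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdbLine("ATOM", 1, "CA", "A", "SER", "A", 1, 0, 0, 0, occ = 0.4),
    pdbLine("ATOM", 2, "CA", "B", "SER", "A", 1, 1, 0, 0, occ = 0.6),
    pdbLine("ATOM", 3, "CB", "B", "SER", "A", 1, 2, 0, 0, occ = 0.5),
    pdbLine("ATOM", 4, "CB", "A", "SER", "A", 1, 3, 0, 0, occ = 0.5)),
    f)
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$name == "CA"], 1.0)  # higher occupancy wins
  expect_equal(a$x[a$name == "CB"], 3.0)  # tie goes to altloc A
})

test_that("locateFlavin recovers a planar ring normal and is equivariant", {
  toy <- makeToyEnzyme(seed = 4)
  fr <- locateFlavin(toy$structure, ligand = toy$ligand)
  ## construction: ring plane perpendicular to the tunnel axis (+x),
  ## normal oriented toward the ligand carboxyl carbon
  expect_equal(as.numeric(fr@ringNormal), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(sqrt(sum(fr@ringNormal^2)), 1, tolerance = 1e-9)
  for (seed in 1:3) {
    R <- withr::with_seed(seed, catalocavity:::.randomRotation())
    tr <- withr::with_seed(seed, runif(3, -20, 20))
    frT <- locateFlavin(transformStructure(toy$structure, R, tr),
                        ligand = toy$ligand)
    expect_equal(frT@n5, as.numeric(R %*% fr@n5 + tr), tolerance = 1e-6)
    expect_equal(frT@ringNormal, as.numeric(R %*% fr@ringNormal),
                 tolerance = 1e-6)
  }
})

test_that("locateFlavin errors on missing or degenerate cofactors", {
  toy <- makeToyEnzyme(seed = 5)
  expect_error(locateFlavin(toy$structure, residueName = "FMN"),
               class = "catalocavity_cofactor_error")
  ## drop ring atoms below the 4-atom minimum
  a <- atoms(toy$structure)
  crippled <- new("ProteinStructure",
                  atoms = a[!(a$resname == "FAD" &
                                a$name %in% c("C4A", "C5A", "C9A")), ],
                  id = "crippled")
  expect_error(locateFlavin(crippled),
               class = "catalocavity_cofactor_error")
})

test_that("ligand truncation keeps the head group and is idempotent", {
  toy <- makeToyEnzyme(seed = 6, ligandCarbons = 18L, tunnelLength = 30)
  isLig <- function(s) {
    a <- atoms(s)
    a[a$resname == "OCA", , drop = FALSE]
  }
  expect_equal(nrow(isLig(toy$structure)), 20L)  # 18 C + 2 O
  t8 <- truncateLigand(toy$structure, toy$ligand, keepCarbons = 8)
  la <- isLig(t8)
  expect_equal(nrow(la), 10L)                    # 8 C + 2 O
  expect_setequal(la$name, c(paste0("C", 1:8), "O1", "O2"))
  ## protein atoms untouched
  expect_equal(sum(!atoms(t8)$het), sum(!atoms(toy$structure)$het))
  ## idempotent
  t8again <- truncateLigand(t8, LigandSpec("OCA", "L", 500L, "C1",
                                           paste0("C", 1:8)),
                            keepCarbons = 8)
  expect_equal(atoms(t8again), atoms(t8))
  ## keepCarbons = chain length leaves the ligand unchanged (already-C8
  ## ligands are already at the target length)
  toy8 <- makeToyEnzyme(seed = 7, ligandCarbons = 8L)
  same <- truncateLigand(toy8$structure, toy8$ligand, keepCarbons = 8)
  expect_equal(atoms(same), atoms(toy8$structure))
})

test_that("ligand truncation rejects bad carbon counts and missing ligands", {
  toy <- makeToyEnzyme(seed = 8)
  expect_error(truncateLigand(toy$structure, toy$ligand, keepCarbons = 9),
               class = "catalocavity_value_error")
  expect_error(truncateLigand(toy$structure, toy$ligand, keepCarbons = 1),
               class = "catalocavity_value_error")
  ghost <- LigandSpec("XYZ", "L", 999L, "C1", paste0("C", 1:4))
  expect_error(truncateLigand(toy$structure, ghost, keepCarbons = 2),
               class = "catalocavity_ligand_error")
})
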