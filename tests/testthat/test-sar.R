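# Ligand-efficiency arithmetic and the bundled reference panel.

test_that("pIC50 <-> IC50 conversion is exact and strictly decreasing", {
  expect_equal(pic50ToIc50uM(6), 1)
  expect_equal(pic50ToIc50uM(3.72), 190, tolerance = 0.01)
  p <- c(2.5, 3.1, 4.8, 7.2)
  expect_equal(6 - log10(pic50ToIc50uM(p)), p, tolerance = 1e-9)
  expect_true(all(diff(pic50ToIc50uM(sort(p))) < 0))
})

test_that("ligand efficiency reproduces the canonical worked values", {
  expect_equal(ligandEfficiency(3.11, 11), 0.40)
  expect_equal(ligandEfficiency(3.51, 18), 0.27)
  expect_equal(ligandEfficiency(0, 20), 0.00)
  expect_error(ligandEfficiency(3.0, 0), "heavyAtoms")
  # linear in pIC50, inverse in heavy atoms (exact algebra, unrounded)
  expect_equal(ligandEfficiency(2 * 3.3, 10, digits = NA),
               2 * ligandEfficiency(3.3, 10, digits = NA))
  expect_equal(ligandEfficiency(3.3, 20, digits = NA),
               ligandEfficiency(3.3, 10, digits = NA) / 2)
})

test_that("reference panel structures parse and carry consistent fields", {
  panel <- phipPanel()
  expect_equal(nrow(panel), 22)
  expect_false(anyNA(panel$smiles))
  expect_equal(sum(panel$censored), 5)
  expect_true(all(is.na(panel$ic50_uM[panel$censored])))
  expect_equal(panel$le,
               ligandEfficiency(panel$pic50, panel$heavy_atoms))
  expect_equal(panel$pic50[panel$compound_id == "11"], 3.89)
})

test_that("recomputed LE matches the tabulated values in >= 15/17 non-censored rows", {
  panel <- phipPanel()
  nc <- panel[!panel$censored, ]
  expect_equal(nrow(nc), 17)
  leRaw <- ligandEfficiency(nc$pic50, nc$heavy_atoms, digits = NA)
  within <- abs(leRaw - nc$le_printed) <= 0.005 + 1e-9
  expect_gte(sum(within), 15)
  # the one documented outlier computes 0.44 against a tabulated 0.45
  expect_equal(ligandEfficiency(3.78, 12), 0.44)
  expect_false(within[nc$compound_id == "6"])
})

test_that("censored rows reproduce their printed LE bounds under <=", {
  panel <- phipPanel()
  cen <- panel[panel$censored, ]
  expect_true(all(ligandEfficiency(cen$pic50, cen$heavy_atoms) <=
                    cen$le_printed + 1e-9))
})
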