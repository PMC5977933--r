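# One-step follow-up enumeration around poised hits.

test_that("thiourea hit 1 expands to ring- and N-substituted analogues", {
  panel <- phipPanel()
  hit1 <- panel$smiles[panel$compound_id == "1"]
  cat1 <- data.frame(id = c("dma", "ma", "tol"),
                     smiles = c(canonicalSmiles("Cc1cccc(N)c1C"), "CN",
                                "Cc1ccccc1N"),
                     functional_class = "amine", available = 1L)
  pr <- proposeAnalogues(hit1, "thiourea", cat1, similarityThreshold = 0)
  cpd6 <- panel$smiles[panel$compound_id == "6"]
  cpd10 <- panel$smiles[panel$compound_id == "10"]
  expect_true(cpd6 %in% pr$product_smiles)
  expect_true(cpd10 %in% pr$product_smiles)
  # deterministic ordering: role, then similarity descending
  expect_true(all(diff(pr$replaced_role) >= 0))
  for (ro in unique(pr$replaced_role))
    expect_true(all(diff(pr$similarity_to_original[pr$replaced_role == ro]) <= 0))
})

test_that("amide hit 2 expands to the dimethoxy analogue (compound 12)", {
  panel <- phipPanel()
  hit2 <- panel$smiles[panel$compound_id == "2"]
  cat2 <- data.frame(id = "dmba",
                     smiles = canonicalSmiles("COc1cccc(OC)c1CN"),
                     functional_class = "amine", available = 1L)
  pr <- proposeAnalogues(hit2, "amide", cat2, similarityThreshold = 0,
                         varyRoles = 2)
  expect_true(panel$smiles[panel$compound_id == "12"] %in% pr$product_smiles)
})

test_that("a catalog holding only the hit's own synthons proposes nothing", {
  panel <- phipPanel()
  hit1 <- panel$smiles[panel$compound_id == "1"]
  own <- data.frame(id = c("a", "b"), smiles = c("Cc1ccccc1N", "N"),
                    functional_class = "amine", available = 1L)
  pr <- proposeAnalogues(hit1, "thiourea", own, similarityThreshold = 1.0)
  expect_equal(nrow(pr), 0)
})

test_that("proposals re-classify as poised for the same reaction (closure)", {
  panel <- phipPanel()
  hit <- panel$smiles[panel$compound_id == "3"]
  pr <- proposeAnalogues(hit, "aminooxazole_carbonitrile", phipSynthons(),
                         similarityThreshold = 0)
  expect_gt(nrow(pr), 0)
  for (p in pr$product_smiles)
    expect_true("aminooxazole_carbonitrile" %in% classifyPoised(p)$reaction)
})

test_that("raising the similarity threshold never adds proposals", {
  panel <- phipPanel()
  hit1 <- panel$smiles[panel$compound_id == "1"]
  syn <- phipSynthons()
  lo <- proposeAnalogues(hit1, "thiourea", syn, similarityThreshold = 0)
  hi <- proposeAnalogues(hit1, "thiourea", syn, similarityThreshold = 0.4)
  expect_true(all(hi$product_smiles %in% lo$product_smiles))
  expect_lte(nrow(hi), nrow(lo))
  # errors and warnings
  expect_error(proposeAnalogues("c1ccccc1", "amide", syn), "not poised")
  noClass <- syn[syn$functional_class == "azide", ]
  expect_warning(proposeAnalogues(hit1, "thiourea", noClass, varyRoles = 1),
                 "no available")
})

test_that("assay annotation is a left join that keeps censoring as bounds", {
  panel <- phipPanel()
  hit2 <- panel$smiles[panel$compound_id == "2"]
  cat2 <- data.frame(id = "dmba",
                     smiles = canonicalSmiles("COc1cccc(OC)c1CN"),
                     functional_class = "amine", available = 1L)
  pr <- proposeAnalogues(hit2, "amide", cat2, similarityThreshold = 0,
                         varyRoles = 2)
  merged <- annotateWithAssay(pr, panel)
  row12 <- merged[merged$product_smiles ==
                    panel$smiles[panel$compound_id == "12"], ]
  expect_equal(row12$pic50, 3.72)
  expect_false(row12$censored)
  # unmatched proposals carry empty assay fields
  empty <- annotateWithAssay(pr, panel[panel$compound_id == "1", ])
  expect_true(all(is.na(empty$pic50)))
  # censored entries stay flagged, never silently numeric
  expect_true(panel$censored[panel$compound_id == "19"])
  # duplicate keys are an error
  expect_error(annotateWithAssay(pr, rbind(panel, panel)), "duplicate")
})
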