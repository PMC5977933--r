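# Property, compatibility and availability filters.

test_that("property filters keep fragment-like records and name the failing rule", {
  rec <- fragmentRecords(
    c("Cc1ccccc1NC(N)=S",                         # compound 1: MW 166, HA 11
      "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC", # ~593 Da alkane
      "[Si](C)(C)(C)C"),                          # silicon: element rule
    id = c("ok", "big", "sil"))
  rep <- applyPropertyFilters(rec)
  expect_true("ok" %in% keptIds(rep))
  rj <- rejections(rep)
  expect_equal(rj$rule[rj$id == "big"], "mw_max") # first failing rule wins
  expect_equal(rj$rule[rj$id == "sil"], "elements")
  # with the weight bound disabled, the same alkane trips the next rule
  rep2 <- applyPropertyFilters(rec[rec$id == "big", ],
                               designThresholds(mw_max = Inf))
  expect_equal(rejections(rep2)$rule, "clogp_max")
})

test_that("empty input yields an empty report", {
  rep <- applyPropertyFilters(fragmentRecords(character(0)))
  expect_length(keptIds(rep), 0)
  expect_equal(nrow(rejections(rep)), 0)
})

test_that("filters are monotone: tightening a bound never grows the kept set", {
  gen <- tinyCatalog(n = 40, seed = 3)
  loose <- keptIds(applyPropertyFilters(gen$records,
                                        designThresholds(mw_max = 400)))
  tight <- keptIds(applyPropertyFilters(gen$records,
                                        designThresholds(mw_max = 250)))
  expect_true(all(tight %in% loose))
})

test_that("an amide-poised fragment with an extra free aniline amine is incompatible", {
  # 4-aminophenyl acetamide: the para NH2 would acylate too
  s <- canonicalSmiles("CC(=O)Nc1ccc(N)cc1")
  ann <- classifyPoised(s, id = "x")
  amide <- ann[ann$reaction == "amide", ][1, ]
  res <- compatibilityFilter(amide, s, id = "x")
  expect_false(res$compatible)
  expect_equal(res$reason, "cross-reactive amine")
})

test_that("clean fragments pass compatibility; id mismatches are errors", {
  s <- "CC(=O)NCc1c(Cl)cccc1Cl"
  ann <- classifyPoised(s, id = "cpd2")
  res <- compatibilityFilter(ann[1, ], s, id = "cpd2")
  expect_true(res$compatible)
  expect_equal(res$reason, "")
  expect_error(compatibilityFilter(ann[1, ], s, id = "other"), "cpd2")
  # heterocycle-poised fragment with no flagged groups
  s3 <- canonicalSmiles("Cc1nc2ccccc2o1")
  ann3 <- classifyPoised(s3)
  res3 <- compatibilityFilter(ann3[ann3$reaction == "benzoxazole", ][1, ], s3)
  expect_true(res3$compatible)
})

test_that("compatibility allowances tolerate the reaction's own product groups", {
  # reductive amination product contains the amine it formed
  s <- canonicalSmiles("CNCc1ccccc1")
  ann <- classifyPoised(s)
  ra <- ann[ann$reaction == "reductive_amination", ][1, ]
  expect_true(compatibilityFilter(ra, s)$compatible)
  # a second free amine elsewhere is one too many
  s2 <- canonicalSmiles("NCCCNCc1ccccc1")
  ann2 <- classifyPoised(s2)
  ra2 <- ann2[ann2$reaction == "reductive_amination", ][1, ]
  expect_false(compatibilityFilter(ra2, s2)$compatible)
})

test_that("availability requires every synthon, exact or by similarity", {
  ann <- classifyPoised("CC(=O)NCc1c(Cl)cccc1Cl", id = "cpd2")
  full <- data.frame(id = c("s1", "s2"),
                     smiles = c("CC(=O)Cl", "NCc1c(Cl)cccc1Cl"),
                     functional_class = c("acyl_chloride", "amine"),
                     available = 1L)
  expect_equal(nrow(availabilityFilter(ann, full)), nrow(ann))
  missingAmine <- full[1, , drop = FALSE]
  expect_equal(nrow(availabilityFilter(ann, missingAmine)), 0)
  expect_warning(availabilityFilter(ann, full[0, ]), "no available")

  # similar mode: 2,3-dimethylaniline stands in for o-toluidine at 0.4
  annT <- classifyPoised(canonicalSmiles("Cc1ccccc1NC(N)=S"), id = "cpd1")
  cat23 <- data.frame(id = c("a", "b"),
                      smiles = c("Cc1cccc(N)c1C", "N"),
                      functional_class = "amine", available = 1L)
  simOK <- availabilityFilter(annT, cat23, mode = "similar", threshold = 0.4)
  expect_equal(nrow(simOK), nrow(annT))
  expect_gt(tanimoto(circularFingerprint("Cc1ccccc1N")[1, ],
                     circularFingerprint(canonicalSmiles("Cc1cccc(N)c1C"))[1, ]),
            0.4)
  expect_equal(nrow(availabilityFilter(annT, cat23, mode = "exact")), 0)
})

test_that("exact mode equals similar mode at threshold 1 on identical catalogs", {
  ann <- classifyPoised("CC(=O)NCc1c(Cl)cccc1Cl", id = "cpd2")
  cat1 <- data.frame(id = c("s1", "s2"),
                     smiles = c("CC(=O)Cl", "NCc1c(Cl)cccc1Cl"),
                     functional_class = c("acyl_chloride", "amine"),
                     available = 1L)
  ex <- availabilityFilter(ann, cat1, mode = "exact")
  si <- availabilityFilter(ann, cat1, mode = "similar", threshold = 1.0)
  expect_equal(ex$reaction, si$reaction)
})
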