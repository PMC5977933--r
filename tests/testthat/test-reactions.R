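# Reaction knowledge base: roster, classification, deconstruction, forward
# synthesis, and the transform invariants.

test_that("built-in roster has 21 uniquely named reactions, 8 linking + 13 heterocycle", {
  lib <- loadReactionLibrary()
  expect_length(lib, 21)
  nms <- vapply(lib, reactionName, character(1))
  expect_false(anyDuplicated(nms) > 0)
  cats <- vapply(lib, reactionCategory, character(1))
  expect_equal(sum(cats == "linking"), 8)
  expect_equal(sum(cats == "heterocycle"), 13)
  for (d in lib) {
    need <- if (reactionCategory(d) == "linking") 2 else 1
    expect_gte(length(synthonClasses(d)), need)
  }
})

test_that("user reaction files subset the roster and are validated", {
  lib <- loadReactionLibrary()
  amideOnly <- Filter(function(d) reactionName(d) == "amide", lib)
  f <- tempfile(fileext = ".yml")
  writeReactionLibrary(amideOnly, f)
  back <- loadReactionLibrary(f)
  expect_length(back, 1)
  expect_equal(reactionName(back[[1]]), "amide")
  # same declarative content round-trips
  expect_equal(back[[1]]@productSmarts, amideOnly[[1]]@productSmarts)
  expect_equal(back[[1]]@synthonClasses, amideOnly[[1]]@synthonClasses)

  # malformed SMARTS -> definition-level error naming the reaction
  bad <- yaml::read_yaml(f)
  bad$reactions[[1]]$product_smarts <- "[Cthis is not smarts"
  f2 <- tempfile(fileext = ".yml")
  yaml::write_yaml(bad, f2)
  expect_error(loadReactionLibrary(f2), "amide")

  # duplicate names -> load error
  dup <- yaml::read_yaml(f)
  dup$reactions <- c(dup$reactions, dup$reactions)
  f3 <- tempfile(fileext = ".yml")
  yaml::write_yaml(dup, f3)
  expect_error(loadReactionLibrary(f3), "duplicate")
})

test_that("an N-benzylamide deconstructs into acid chloride + amine", {
  ann <- classifyPoised("CC(=O)NCc1c(Cl)cccc1Cl", id = "cpd2")
  expect_true("amide" %in% ann$reaction)
  sets <- deconstruct("CC(=O)NCc1c(Cl)cccc1Cl", "amide")
  expect_length(sets, 1)
  expect_setequal(sets[[1]], c("CC(=O)Cl", "NCc1c(Cl)cccc1Cl"))
})

test_that("a phenylthiourea deconstructs into arylamine + ammonia equivalents", {
  sets <- deconstruct(canonicalSmiles("Cc1ccccc1NC(N)=S"), "thiourea")
  expect_length(sets, 1)
  expect_setequal(sets[[1]], c(canonicalSmiles("Cc1ccccc1N"), "N"))
})

test_that("unpoised inputs give empty results, bad inputs give errors", {
  expect_equal(nrow(classifyPoised("c1ccccc1")), 0)
  expect_length(deconstruct("C", "amide"), 0)
  expect_error(deconstruct("C", "no_such_reaction"), "unknown reaction")
  expect_error(classifyPoised("not-a-smiles(", id = "x1"), "x1")
  expect_error(forwardSynthesize("amide", "CC(=O)Cl"), "needs 2 synthons")
})

test_that("forward synthesis reproduces known products and rejects role mismatches", {
  expect_equal(forwardSynthesize("thiourea", c("Cc1ccccc1N", "N")),
               canonicalSmiles("Cc1ccccc1NC(N)=S"))
  expect_equal(forwardSynthesize("aminooxazole_carbonitrile", "CC(C)CC(=O)Cl"),
               canonicalSmiles("Nc1oc(CC(C)C)nc1C#N"))
  expect_true(is.na(forwardSynthesize("amide", c("c1ccccc1", "c1ccccc1"))))
})

test_that("symmetry-unique annotation counts agree with a bond-enumeration oracle", {
  # oracle: count acyclic C(=O)-N bonds by direct graph inspection
  amideBondCount <- function(smiles) {
    m <- poisedfrag:::.molFromSmiles(canonicalSmiles(smiles))
    b <- m$bonds
    nbrs <- function(i) c(b$a2[b$a1 == i], b$a1[b$a2 == i])
    ring <- function(i, j) { # bond in ring iff endpoints stay connected without it
      keep <- !((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
      sub <- m; sub$bonds <- b[keep, , drop = FALSE]
      comp <- poisedfrag:::.molComponents(sub)
      any(vapply(comp, function(cc) i %in% cc && j %in% cc, logical(1)))
    }
    cnt <- 0
    for (r in seq_len(nrow(b))) {
      for (swap in c(FALSE, TRUE)) {
        ci <- if (swap) b$a2[r] else b$a1[r]
        ni <- if (swap) b$a1[r] else b$a2[r]
        if (m$atoms$elem[ci] != "C" || m$atoms$elem[ni] != "N") next
        if (b$order[r] != 1 || ring(ci, ni)) next
        hasCO <- any(vapply(nbrs(ci), function(k)
          m$atoms$elem[k] == "O" &&
            any((b$a1 == ci & b$a2 == k | b$a1 == k & b$a2 == ci) & b$order == 2),
          logical(1)))
        if (hasCO) cnt <- cnt + 1
      }
    }
    cnt
  }
  cases <- c("NC(=O)CC(N)=O",            # malonamide: two equivalent amides
             "CC(=O)NCCNC(C)=O",         # diacylated diamine
             "CC(=O)NC",                 # one amide
             "O=C1CCCN1C")               # lactam only: zero acyclic
  for (s in cases) {
    ann <- classifyPoised(s)
    expect_equal(sum(ann$reaction == "amide"), amideBondCount(s), info = s)
  }
})

test_that("classification is deterministic and ordered", {
  a <- classifyPoised("CC(=O)NCc1c(OC)cccc1OC", id = "x")
  b <- classifyPoised("CC(=O)NCc1c(OC)cccc1OC", id = "x")
  expect_identical(a, b)
  expect_equal(a$reaction, sort(a$reaction))
  # matched atoms are valid 0-based indices
  nAtoms <- heavyAtoms("CC(=O)NCc1c(OC)cccc1OC")
  for (ma in a$matched_atoms) {
    expect_true(all(ma >= 0 & ma < nAtoms))
  }
  for (syn in a$synthons) expect_false(anyNA(canonicalSmiles(syn)))
})

test_that("generator products classify as poised for their generating reaction (closure)", {
  gen <- generateSyntheticCatalog(n = 40, seed = 11)
  for (i in seq_len(nrow(gen$catalog))) {
    lab <- gen$labels$reaction[i]
    ann <- classifyPoised(gen$catalog$smiles[i])
    if (lab == "decoy") expect_equal(nrow(ann), 0, info = gen$catalog$smiles[i])
    else expect_true(lab %in% ann$reaction, info = gen$catalog$smiles[i])
  }
})
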