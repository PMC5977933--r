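# USRCAT descriptors, similarity kernel, clustering, max-min selection.

test_that("conformer embedding is reproducible and includes hydrogens", {
  a <- embedConformer("C", seed = 7)
  b <- embedConformer("C", seed = 7)
  expect_identical(unclass(a), unclass(b))
  expect_equal(nrow(a), 5) # CH4
  expect_equal(sum(attr(a, "elem") == "H"), 4)
  D <- as.matrix(dist(a))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_error(embedConformer("!!bad!!"), "unparsable")
})

test_that("USRCAT moments match the closed form on 3 collinear equidistant points", {
  coords <- cbind(c(-2, 0, 2), 0, 0)
  d <- usrcatDescriptor(coords)
  # all-atoms block, centroid reference: distances {2, 0, 2}
  mu <- mean(c(2, 0, 2))
  sd0 <- sqrt(mean((c(2, 0, 2) - mu)^2))
  m3 <- mean((c(2, 0, 2) - mu)^3)
  expect_equal(d[1:3], c(mu, sd0, sign(m3) * abs(m3)^(1 / 3)), tolerance = 1e-12)
  # closest-to-centroid reference is the middle point: distances {2, 0, 2}
  expect_equal(d[4:6], d[1:3], tolerance = 1e-12)
  # farthest-from-centroid reference (an end): distances {0, 2, 4}
  mu2 <- 2; sd2 <- sqrt(mean((c(0, 2, 4) - 2)^2))
  expect_equal(d[7:8], c(mu2, sd2), tolerance = 1e-12)
  # empty pharmacophore subsets give zero blocks
  expect_true(all(d[13:60] == 0))
  expect_error(usrcatDescriptor(coords[1:2, ]), "3 atoms")
})

test_that("USRCAT is invariant to rotation and translation", {
  co <- embedConformer("CC(=O)NCc1c(Cl)cccc1Cl", seed = 7)
  th <- 0.93
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- co %*% R + matrix(rep(c(5, -3, 2), each = nrow(co)), ncol = 3)
  expect_lt(max(abs(usrcatDescriptor(co) - usrcatDescriptor(moved))), 1e-8)
})

test_that("benzene's hydrophobic and aromatic blocks coincide; descriptors have length 60", {
  d <- usrcatFromSmiles("c1ccccc1", seed = 7)
  expect_length(d, 60)
  expect_true(all(is.finite(d)))
  expect_equal(d[13:24], d[25:36]) # same atom subset
  expect_false(all(d[1:12] == 0))
  # a molecule with no aromatic atoms has an all-zero aromatic block
  dal <- usrcatFromSmiles("CCO", seed = 7)
  expect_true(all(dal[25:36] == 0))
})

test_that("USRCAT similarity kernel is a bounded symmetric similarity", {
  a <- usrcatFromSmiles("Cc1ccccc1NC(N)=S", 7)
  b <- usrcatFromSmiles("CC(=O)NCc1c(Cl)cccc1Cl", 7)
  expect_equal(usrcatSimilarity(a, a), 1)
  expect_equal(usrcatSimilarity(a, b), usrcatSimilarity(b, a))
  expect_gt(usrcatSimilarity(a, b), 0)
  expect_lte(usrcatSimilarity(a, b), 1)
  x <- numeric(60); y <- numeric(60); y[1] <- 60
  expect_equal(usrcatSimilarity(x, y), 0.5) # 1/(1 + 60/60)
  expect_error(usrcatSimilarity(a[1:10], b), "length 60")
})

test_that("Butina clustering merges identicals and splits unrelated molecules", {
  cl <- clusterFingerprints(c("CCO", "OCC"), ids = c("a", "b"), cutoff = 0.3)
  expect_length(cl$centroids, 1)
  cl2 <- clusterFingerprints(
    c("CCCCCCCC", "c1ccc2ccccc2c1", "CC(=O)NCc1ccccc1"),
    ids = c("alkane", "naphthalene", "amide"), cutoff = 0.3)
  expect_length(cl2$centroids, 3)
  # each centroid is a member of its own cluster
  expect_true(all(cl2$assignments[cl2$centroids] == seq_along(cl2$centroids)))
  # every id assigned exactly once
  expect_setequal(names(cl2$assignments), c("alkane", "naphthalene", "amide"))
})

test_that("cluster count is non-increasing as the cutoff loosens", {
  gen <- tinyCatalog(n = 25, seed = 5)
  smi <- gen$catalog$smiles; ids <- gen$catalog$id
  k1 <- length(clusterFingerprints(smi, ids, cutoff = 0.2)$centroids)
  k2 <- length(clusterFingerprints(smi, ids, cutoff = 0.5)$centroids)
  k3 <- length(clusterFingerprints(smi, ids, cutoff = 0.8)$centroids)
  expect_true(k1 >= k2 && k2 >= k3)
})

test_that("greedy max-min picks the extremes of a line and is exhaustive at k = n", {
  pts <- c(a = 0, b = 1, c = 9, d = 10)
  D <- as.matrix(dist(pts))
  expect_setequal(selectDiverse(D, 2), c("a", "d")) # brute-force optimum
  expect_setequal(selectDiverse(D, 4), names(pts))
  expect_error(selectDiverse(D, 5), "exceeds")
})

test_that("greedy max-min dominates random selection in min pairwise distance", {
  set.seed(99)
  wins <- 0
  for (t in 1:40) {
    X <- matrix(runif(30 * 4), ncol = 4)
    rownames(X) <- sprintf("p%02d", 1:30)
    D <- as.matrix(dist(X))
    g <- minPairwiseDistance(D, selectDiverse(D, 6))
    r <- minPairwiseDistance(D, sample(rownames(X), 6))
    if (g >= r) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
})
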