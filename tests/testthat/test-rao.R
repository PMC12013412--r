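test_that("gower_dissimilarity on a single binary trait is 0/1 structured", {
  tr <- matrix(c(1, 0, 0, 0), ncol = 1,
               dimnames = list(paste0("s", 1:4), "producer"))
  d <- gower_dissimilarity(tr)
  expect_equal(dim(d), c(4L, 4L))
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d["s1", "s2"], 1)  # producer vs non-producer
  expect_equal(d["s2", "s3"], 0)  # both lack the trait: symmetric match
  expect_true(isSymmetric(d))
})

test_that("identical trait rows and range extremes behave as expected", {
  # identical trait rows: similarity 1 everywhere, d = 0
  tr <- matrix(rep(c(1, 0), each = 3), nrow = 3,
               dimnames = list(paste0("s", 1:3), c("t1", "t2")))
  expect_equal(gower_dissimilarity(tr), matrix(0, 3, 3), ignore_attr = TRUE)
  # all-constant quantitative traits leave nothing to compare
  trq <- matrix(3.5, 3, 1, dimnames = list(paste0("s", 1:3), "q"))
  expect_warning(expect_error(gower_dissimilarity(trq, "quantitative"),
                              "no informative"),
                 "zero range")
  tr2 <- matrix(c(0, 10, 0, 2, 2, 2), ncol = 2,
                dimnames = list(paste0("s", 1:3), c("q", "const")))
  expect_warning(d2 <- gower_dissimilarity(tr2, c("quantitative", "quantitative")),
                 "zero range")
  expect_equal(d2["s1", "s2"], 1)  # opposite range extremes
  expect_equal(d2["s1", "s3"], 0)  # identical informative values
})

test_that("gower_dissimilarity agrees with cluster::daisy", {
  set.seed(37)
  x <- cbind(q1 = runif(8), q2 = runif(8, -3, 5))
  rownames(x) <- paste0("s", 1:8)
  d <- gower_dissimilarity(x, kinds = c("quantitative", "quantitative"))
  ref <- as.matrix(cluster::daisy(as.data.frame(x), metric = "gower"))
  expect_equal(d^2, ref, tolerance = 1e-10, ignore_attr = TRUE)

  b <- cbind(t1 = c(1, 1, 0, 0, 1), t2 = c(0, 1, 0, 1, 1))
  rownames(b) <- paste0("s", 1:5)
  db <- gower_dissimilarity(b, kinds = c("binary", "binary"))
  refb <- as.matrix(cluster::daisy(
    data.frame(t1 = factor(b[, 1]), t2 = factor(b[, 2])), metric = "gower"))
  expect_equal(db^2, refb, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rao_q matches a brute-force double loop and the Simpson limit", {
  set.seed(41)
  n <- 6
  a <- rexp(n); a <- a / sum(a)
  com <- community(a, paste0("s", 1:n))
  tr <- matrix(runif(n * 2), ncol = 2,
               dimnames = list(com$species, c("q1", "q2")))
  d <- gower_dissimilarity(tr)
  brute <- 0
  for (i in 1:n) for (j in 1:n) brute <- brute + d[i, j] * a[i] * a[j]
  expect_equal(rao_q(com, d), brute, tolerance = 1e-12)

  # maximally dissimilar traits: Q equals Simpson's D
  d1 <- 1 - diag(n); dimnames(d1) <- list(com$species, com$species)
  expect_equal(rao_q(com, d1), simpson_diversity(com), tolerance = 1e-12)
  expect_equal(community_fr(com, d1), 0, tolerance = 1e-12)

  # d identically zero: FR equals D
  d0 <- matrix(0, n, n, dimnames = list(com$species, com$species))
  expect_equal(rao_q(com, d0), 0)
  expect_equal(community_fr(com, d0), simpson_diversity(com))
})

test_that("community_fr keystone closed form (n-1)(n-2)/n^2 holds", {
  for (n in c(2, 4, 10, 100)) {
    ids <- paste0("s", seq_len(n))
    com <- community(rep(1 / n, n), ids)
    tr <- matrix(c(1, rep(0, n - 1)), ncol = 1,
                 dimnames = list(ids, "producer"))
    d <- gower_dissimilarity(tr)
    expect_equal(community_fr(com, d), (n - 1) * (n - 2) / n^2,
                 tolerance = 1e-12)
  }
})

test_that("dissimilarity validation rejects malformed matrices", {
  com <- community(c(0.5, 0.5), c("a", "b"))
  bad <- matrix(c(0, 0.5, 0.7, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(rao_q(com, bad), "symmetric")
  expect_error(rao_q(com, matrix(0, 3, 3)), "wrong dimension")
})

test_that("keystone series shows the divergence between frameworks", {
  ks <- keystone_series(50, m = 100)
  expect_equal(nrow(ks), 50L)
  # single-trait measures: reference constant, sample/abundance decreasing
  expect_equal(ks$fr_reference, rep(-log(100), 50))
  expect_equal(ks$fr_sample, -log(ks$n))
  expect_equal(ks$fr_abundance, ks$fr_sample)  # uniform-abundance equivalence
  expect_true(all(diff(ks$fr_sample) < 0))
  # community-level FR: 0 at n = 1, non-decreasing, strictly rising from n = 3
  expect_equal(ks$community_fr[1], 0)
  expect_true(all(diff(ks$community_fr) >= 0))
  expect_true(all(diff(ks$community_fr[-(1:2)]) > 0))
  expect_true(all(ks$community_fr <= 1))
})
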