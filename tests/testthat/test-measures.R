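uniform_community <- function(n, ids = paste0("sp", seq_len(n))) {
  community(rep(1 / n, n), ids)
}

test_that("fr_sample reproduces the keystone and uniform anchors", {
  # single producer among 100 species: minimal redundancy -log(100)
  com <- uniform_community(100)
  prof <- functional_profile(c(1, rep(0, 99)), com$species, "F")
  expect_equal(fr_sample(prof, com), -log(100))
  # equal positive shares: maximal redundancy 0, any abundances
  com4 <- community(c(0.4, 0.3, 0.2, 0.1), paste0("sp", 1:4))
  prof4 <- functional_profile(rep(2, 4), com4$species, "F")
  expect_equal(fr_sample(prof4, com4), 0)
  # hand-derived: H(0.5, 0.25, 0.25) - log 4
  prof5 <- functional_profile(c(2, 1, 1, 0), com4$species, "F")
  expect_equal(fr_sample(prof5, com4), 1.0397208 - log(4), tolerance = 1e-6)
})

test_that("fr_reference is constant in sample richness with a fixed m", {
  ref <- function_reference("F", paste0("sp", 1:100))
  for (n in c(1, 7, 42, 100)) {
    com <- uniform_community(n)
    prof <- functional_profile(c(1, rep(0, n - 1)), com$species, "F")
    expect_equal(fr_reference(prof, ref), -log(100))
  }
  # 4 equal producers against m = 7
  ref7 <- function_reference("F", paste0("sp", 1:7))
  prof <- functional_profile(rep(1, 4), paste0("sp", 1:4), "F")
  expect_equal(fr_reference(prof, ref7), log(4) - log(7))
  # all m present and equal: maximum 0
  prof_all <- functional_profile(rep(3, 7), paste0("sp", 1:7), "F")
  expect_equal(fr_reference(prof_all, ref7), 0)
})

test_that("fr_reference rejects producers outside the reference", {
  ref <- function_reference("F", c("a", "b"))
  prof <- functional_profile(c(a = 1, b = 1, z = 2), function_id = "F")
  expect_error(fr_reference(prof, ref), "not in the function reference")
  # a zero-contribution species outside the reference is fine
  prof0 <- functional_profile(c(a = 1, b = 1, z = 0), function_id = "F")
  expect_equal(fr_reference(prof0, ref), 0)
})

test_that("fr_abundance anchors: proportional, keystone, hand-derived", {
  ids <- paste0("sp", 1:3)
  com <- community(c(0.25, 0.25, 0.5), ids)
  # fi proportional to ai for every species: shares equal abundances
  prof_prop <- functional_profile(c(0.25, 0.25, 0.5) * 7, ids, "F")
  expect_equal(fr_abundance(prof_prop, com), 0)
  # shares (0.5, 0.5, 0) vs abundances (0.25, 0.25, 0.5)
  prof <- functional_profile(c(1, 1, 0), ids, "F")
  expect_equal(fr_abundance(prof, com), -log(2))
  # uniform abundances, single producer
  com100 <- uniform_community(100)
  prof100 <- functional_profile(c(1, rep(0, 99)), com100$species, "F")
  expect_equal(fr_abundance(prof100, com100), -log(100))
})

test_that("interdependency anchors: proportionality, singleton, hand value", {
  ids <- paste0("sp", 1:4)
  com <- community(c(0.1, 0.2, 0.3, 0.4), ids)
  # flux proportional to abundance on the producer set J
  prof <- functional_profile(c(0, 0.2, 0.3, 0) * 3, ids, "F")
  expect_equal(fr_interdependency(prof, com), 0)
  # single producer: both restricted vectors are (1)
  prof1 <- functional_profile(c(0, 0, 5, 0), ids, "F")
  expect_equal(fr_interdependency(prof1, com), 0)
  # f_J = (0.8, 0.2), a_J = (0.3, 0.3) -> a~ = (0.5, 0.5)
  com3 <- community(c(0.3, 0.3, 0.4), paste0("sp", 1:3))
  prof3 <- functional_profile(c(0.8, 0.2, 0), paste0("sp", 1:3), "F")
  expect_equal(fr_interdependency(prof3, com3),
               0.8 * log(1.6) + 0.2 * log(0.4))
})

test_that("no producers yields NA from each measure", {
  com <- uniform_community(3)
  prof <- functional_profile(rep(0, 3), com$species, "F")
  ref <- function_reference("F", com$species)
  expect_true(is.na(fr_sample(prof, com)))
  expect_true(is.na(fr_reference(prof, ref)))
  expect_true(is.na(fr_abundance(prof, com)))
  expect_true(is.na(fr_interdependency(prof, com)))
})

test_that("misaligned species sets raise a validation error", {
  com <- uniform_community(3)
  prof <- functional_profile(c(1, 1), paste0("other", 1:2), "F")
  expect_error(fr_sample(prof, com), "species sets differ")
})

test_that("measures respect bounds and iff-zero conditions on random cases", {
  set.seed(7)
  for (i in 1:100) {
    case <- random_case(n = sample(3:40, 1))
    n <- length(case$com$species)
    k <- length(case$producers)
    fs <- fr_sample(case$prof, case$com)
    fa <- fr_abundance(case$prof, case$com)
    ii <- fr_interdependency(case$prof, case$com)
    expect_lte(fs, 1e-12)
    expect_gte(fs, -log(n) - 1e-12)
    expect_lte(fa, 1e-12)
    expect_gte(ii, -1e-12)
    # minimal sample FR iff a single producer
    if (k == 1) expect_equal(fs, -log(n)) else expect_gt(fs, -log(n))
    # reference bounds with a superset reference
    m <- n + 5
    ref <- function_reference("F", paste0("sp", seq_len(m)))
    fref <- fr_reference(case$prof, ref)
    expect_lte(fref, 1e-12)
    expect_gte(fref, -log(m) - 1e-12)
    if (k == 1) expect_equal(fref, -log(m))
  }
})

test_that("uniform abundances make sample and abundance FR coincide", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    com <- uniform_community(n)
    f <- rexp(n) * rbinom(n, 1, 0.7)
    if (sum(f) == 0) f[1] <- 1
    prof <- functional_profile(f, com$species, "F")
    expect_equal(fr_sample(prof, com), fr_abundance(prof, com),
                 tolerance = 1e-12)
  }
})

test_that("proportional producers give the log-total-abundance closed form", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    case <- random_case(n)
    com <- case$com
    J <- case$producers
    f <- numeric(n)
    f[J] <- 4.2 * com$abundance[J]  # f proportional to a on J
    prof <- functional_profile(f, com$species, "F")
    A <- sum(com$abundance[J])
    expect_equal(fr_abundance(prof, com), log(A), tolerance = 1e-12)
    # cross-check via the brute-force KL oracle
    sh <- f / sum(f)
    expect_equal(-naive_kl(sh, com$abundance), log(A), tolerance = 1e-12)
    expect_equal(fr_interdependency(prof, com), 0, tolerance = 1e-12)
  }
})

test_that("vectorised measures agree with the naive KL oracle", {
  set.seed(17)
  for (i in 1:50) {
    case <- random_case(n = sample(2:25, 1))
    sh <- case$prof$contribution / sum(case$prof$contribution)
    a <- case$com$abundance
    n <- length(a)
    expect_equal(fr_sample(case$prof, case$com),
                 -naive_kl(sh, rep(1 / n, n)), tolerance = 1e-12)
    expect_equal(fr_abundance(case$prof, case$com),
                 -naive_kl(sh, a), tolerance = 1e-12)
    J <- sh > 0
    expect_equal(fr_interdependency(case$prof, case$com),
                 naive_kl(sh[J] / sum(sh[J]), a[J] / sum(a[J])),
                 tolerance = 1e-12)
  }
})

test_that("global interdependency is the median with NA handling", {
  expect_equal(fr_global_interdependency(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(fr_global_interdependency(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  expect_equal(fr_global_interdependency(0.5), 0.5)
  expect_equal(fr_global_interdependency(c(NA, 0.3, NA, 0.1)), 0.2)
  expect_true(is.na(fr_global_interdependency(c(NA_real_, NA_real_))))
  expect_true(is.na(fr_global_interdependency(c(0.1, NA), min_count = 2)))
})

test_that("fr_measures composes the measures with consistent provenance", {
  # keystone: n = m = 100, one producer
  com <- uniform_community(100)
  prof <- functional_profile(c(1, rep(0, 99)), com$species, "F")
  ref <- function_reference("F", com$species)
  row <- fr_measures(prof, com, ref)
  expect_equal(row$fr_sample, -log(100))
  expect_equal(row$fr_reference, -log(100))
  expect_equal(row$fr_abundance, -log(100))
  expect_equal(row$interdependency, 0)
  expect_equal(row$k, 1L)
  expect_equal(row$missing_reason, "none")

  # proportional producers with summed abundance 0.6
  ids <- paste0("sp", 1:5)
  a <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  com5 <- community(a, ids)
  f <- c(2 * a[1:3], 0, 0)
  row2 <- fr_measures(functional_profile(f, ids, "F"), com5,
                      function_reference("F", ids))
  expect_equal(row2$producer_abundance_sum, 0.6)
  expect_equal(row2$fr_abundance, log(0.6))
  expect_equal(row2$interdependency, 0)

  # total output zero: everything missing, nothing raised
  row3 <- fr_measures(functional_profile(rep(0, 5), ids, "F"), com5,
                      function_reference("F", ids))
  expect_true(all(is.na(c(row3$fr_sample, row3$fr_reference,
                          row3$fr_abundance, row3$interdependency))))
  expect_equal(row3$missing_reason, "no_producers")
  expect_equal(row3$k, 0L)

  # uptake status forces missingness
  row4 <- fr_measures(functional_profile(f, ids, "F"), com5,
                      status = "uptake_detected")
  expect_equal(row4$missing_reason, "uptake_detected")
  expect_true(is.na(row4$fr_sample))
})
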