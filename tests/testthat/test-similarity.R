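test_that("Shannon entropy matches hand values and the summation oracle", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1)); p <- p / sum(p)
    expect_equal(shannon_entropy(p), oracle_entropy(p), tolerance = 1e-12)
  }
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("joint distributions tally co-occurrences correctly", {
  # identical sequences concentrate on the diagonal with equal marginals
  set.seed(6)
  a <- runif(500)
  jd <- joint_distribution(a, a, n_levels = 8)
  expect_equal(jd$p, jd$q)
  expect_equal(sum(diag(jd$pq)), 1, tolerance = 1e-12)
  expect_equal(rowSums(jd$pq), jd$p, tolerance = 1e-9)
  expect_equal(colSums(jd$pq), jd$q, tolerance = 1e-9)

  # 4-element toy case against a hand-tallied 2x2 table
  a4 <- c(0.1, 0.9, 0.1, 0.9)
  b4 <- c(0.2, 0.8, 0.8, 0.1)
  jd4 <- joint_distribution(a4, b4, n_levels = 2)
  # pairs: (lo,lo), (hi,hi), (lo,hi), (hi,lo) -> each cell 1/4
  expect_equal(jd4$pq, matrix(0.25, 2, 2))

  expect_error(joint_distribution(1:3 / 3, 1:4 / 4), "equal length")
})

test_that("independent sequences factorize within sampling error", {
  set.seed(7)
  n <- 1e5
  jd <- joint_distribution(runif(n), runif(n), n_levels = 8)
  expect_lt(max(abs(jd$pq - outer(jd$p, jd$q))), 0.01)
  expect_lt(mutual_information(jd), 0.01)
})

test_that("mutual information matches closed-form arithmetic", {
  # MI of a variable with itself is its entropy
  set.seed(8)
  a <- runif(2000)
  jd <- joint_distribution(a, a, n_levels = 16)
  expect_equal(mutual_information(jd), shannon_entropy(jd$p), tolerance = 1e-12)

  # printed 2x2 joint: hand evaluation of H(p) + H(q) - H(p,q)
  pq <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  jd2 <- structure(list(p = rowSums(pq), q = colSums(pq), pq = pq,
                        n_levels = 2L), class = "joint_distribution")
  expected <- 1 + 1 - (-(0.8 * log2(0.4) + 0.2 * log2(0.1)))
  expect_equal(mutual_information(jd2), expected, tolerance = 1e-12)
})

test_that("HOG-based MI is maximal at self and drops under misalignment", {
  ph <- generate_phantom_pair(size = 64, seed = 10, noise_sd = 0)
  img <- ph$fixed
  d <- hog_to_distribution(compute_hog(img), 64)
  self_mi <- mi_hog(img, img)
  expect_equal(self_mi, shannon_entropy(d), tolerance = 1e-12)

  rot90 <- image_grid(t(img$pixels)[ncol(img$pixels):1, ])
  expect_lt(mi_hog(img, rot90), self_mi)

  ph2 <- generate_phantom_pair(size = 64, seed = 10,
                               true_transform = rigid_transform(3, 0, 0))
  aligned <- resample(ph2$moving, inverse_transform(ph2$truth))
  off <- resample(ph2$moving, inverse_transform(rigid_transform(0, 0, 0)))
  expect_gt(mi_hog(ph2$fixed, aligned), mi_hog(ph2$fixed, off))
})

test_that("intensity MI matches a hand-computed toy joint table", {
  img <- smooth_image(32)
  jd_self <- joint_distribution(hogreg:::minmax_unit(img$pixels),
                                hogreg:::minmax_unit(img$pixels), 64)
  expect_equal(mi_intensity(img, img), shannon_entropy(jd_self$p),
               tolerance = 1e-12)

  # 4x4 toy pair, 2 levels: hand-tallied joint counts
  a <- image_grid(matrix(c(0, 0, 8, 8,  0, 0, 8, 8,
                           0, 0, 8, 8,  0, 0, 8, 8), 4, 4))
  b <- image_grid(matrix(c(1, 1, 9, 9,  1, 1, 9, 9,
                           9, 9, 1, 1,  9, 9, 1, 1), 4, 4))
  # half the low-a pixels see low-b, half see high-b (and symmetrically):
  # joint = 1/4 in every cell -> MI = 0
  expect_equal(mi_intensity(a, b, n_levels = 2), 0, tolerance = 1e-12)

  expect_equal(mi_intensity(image_grid(matrix(3, 8, 8)), smooth_image(8)), 0)
})

test_that("intensity MI of unrelated noise is near zero", {
  set.seed(9)
  a <- image_grid(matrix(runif(64 * 64), 64, 64))
  b <- image_grid(matrix(runif(64 * 64), 64, 64))
  expect_lt(mi_intensity(a, b, n_levels = 8), 0.05)
})

test_that("MI is symmetric and bounded by the marginal entropies", {
  set.seed(10)
  for (i in 1:30) {
    nl <- sample(2:12, 1)
    pq <- matrix(rexp(nl * nl), nl, nl); pq <- pq / sum(pq)
    jd <- structure(list(p = rowSums(pq), q = colSums(pq), pq = pq,
                         n_levels = nl), class = "joint_distribution")
    jdt <- structure(list(p = colSums(pq), q = rowSums(pq), pq = t(pq),
                          n_levels = nl), class = "joint_distribution")
    mi <- mutual_information(jd)
    expect_gte(mi, -1e-9)
    expect_lte(mi, min(shannon_entropy(jd$p), shannon_entropy(jd$q)) + 1e-9)
    expect_identical(mi, mutual_information(jdt))
  }
})
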