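test_that("uncertainty scores follow the least-confident closed form", {
  p <- rbind(c(0.5, 0.5), c(1.0, 0.0), c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(uncertainty_scores(p), c(0.5, 0.0, 0.3, 0.2), tolerance = 1e-12)
  # three classes: bounded by 1 - 1/n_classes
  p3 <- rbind(c(1, 1, 1) / 3, c(0.5, 0.25, 0.25))
  expect_equal(uncertainty_scores(p3), c(1 - 1 / 3, 0.5), tolerance = 1e-12)
  expect_error(uncertainty_scores(rbind(c(0.5, 0.4))), "sum to 1")
  expect_error(uncertainty_scores(rbind(c(1.2, -0.2))), "non-negative")
})

test_that("mixing weight implements both conventions and their boundaries", {
  # pool 900, data 100
  expect_equal(mixing_weight(100, 900), 0.9, tolerance = 1e-12)
  expect_equal(mixing_weight(100, 900, convention = "literal"), 0.1,
               tolerance = 1e-12)
  # symmetry point
  expect_equal(mixing_weight(500, 500), 0.5)
  expect_equal(mixing_weight(500, 500, convention = "literal"), 0.5)
  # exhausted pool: diversity-first collapses to pure uncertainty
  expect_equal(mixing_weight(10, 0), 0.0)
  expect_error(mixing_weight(0, 5), ">= 1")
  expect_error(mixing_weight(1, -1), ">= 0")
})

test_that("similarity scores map distance onto (0, 1] and are max-monotone", {
  est <- rbind(c(0, 0), c(3, 4))
  expect_equal(similarity_scores(rbind(c(0, 0)), est), 1.0)
  expect_equal(similarity_scores(rbind(c(3, 0)), rbind(c(0, 0))), 0.25) # d = 3
  expect_equal(similarity_scores(rbind(c(3, 0)), rbind(c(0, 0)), map = "exp"),
               exp(-3), tolerance = 1e-12)

  set.seed(21)
  cand <- matrix(rnorm(40), 20, 2)
  base <- matrix(rnorm(10), 5, 2)
  s1 <- similarity_scores(cand, base)
  s2 <- similarity_scores(cand, rbind(base, matrix(rnorm(6), 3, 2)))
  expect_true(all(s2 >= s1 - 1e-15)) # adding points never lowers a score
  expect_true(all(s1 > 0 & s1 <= 1))

  expect_error(similarity_scores(cand, base[0, , drop = FALSE]), "non-empty")
  expect_error(similarity_scores(cand, matrix(0, 2, 3)), "column space")
})

test_that("final scores compose the two terms with the mixing weight", {
  expect_equal(final_scores(0.5, 1.0, 0.5), 0.25, tolerance = 1e-12)
  u <- c(0.2, 0.4)
  s <- c(0.9, 0.1)
  expect_equal(final_scores(u, s, 0), u)        # alpha 0 -> pure uncertainty
  expect_equal(final_scores(u, s, 1), 1 - s)    # alpha 1 -> pure diversity
  expect_equal(final_scores(u, s, 0.3), 0.3 * (1 - s) + 0.7 * u,
               tolerance = 1e-12)
  expect_error(final_scores(u, s[1], 0.5), "equal length")
  expect_error(final_scores(u, s, 1.5), "\\[0, 1\\]")
})

test_that("rank_batch matches the brute-force greedy oracle exactly", {
  set.seed(2024)
  for (case in 1:40) {
    p <- sample(2:10, 1)
    n_pool <- sample(5:50, 1)
    n_train <- sample(2:20, 1)
    batch <- sample(1:10, 1)
    pool <- matrix(rnorm(n_pool * p), n_pool, p)
    train <- matrix(rnorm(n_train * p), n_train, p)
    clf <- mock_logreg(rnorm(p), intercept = rnorm(1))
    conv <- sample(c("diversity_first", "literal"), 1)
    smap <- sample(c("inverse", "exp"), 1)
    got <- rank_batch(clf, pool, train, batch,
                      alpha_convention = conv, similarity_map = smap)
    want <- oracle_rank_batch(clf, pool, train, batch,
                              alpha_convention = conv, similarity_map = smap)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("rank_batch returns distinct indices, deterministically", {
  set.seed(9)
  pool <- matrix(rnorm(60), 30, 2)
  train <- matrix(rnorm(10), 5, 2)
  clf <- mock_logreg(c(1, -1))
  s1 <- rank_batch(clf, pool, train, 10)
  s2 <- rank_batch(clf, pool, train, 10)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 10)
  # batch >= pool returns the whole pool
  all_idx <- rank_batch(clf, pool, train, 100)
  expect_setequal(all_idx, seq_len(30))
})

test_that("a selected candidate suppresses its near-duplicates within a batch", {
  # twin points far from the training data, equal uncertainty by symmetry:
  # once one twin is selected the other's similarity jumps to ~1 and a
  # third, less attractive singleton is taken before it
  train <- rbind(c(0, 0))
  twin <- c(10, 10)
  single <- c(-8, 8)
  pool <- rbind(twin, twin, single)
  clf <- mock_logreg(c(0, 0)) # all candidates equally uncertain (p = 0.5)
  sel <- rank_batch(clf, pool, train, 3)
  expect_equal(sel[1], 1L) # first twin (lowest index on the tie)
  expect_equal(sel[2], 3L) # the singleton overtakes the second twin
  expect_equal(sel[3], 2L) # duplicate selected last

  # an exact duplicate of a training point has similarity 1 and goes last
  pool2 <- rbind(c(0, 0), c(5, 5), c(-5, 5))
  sel2 <- rank_batch(clf, pool2, train, 3)
  expect_equal(sel2[3], 1L)
})

test_that("rank_batch scores stay finite and inside [0, 1], and log exports", {
  set.seed(33)
  pool <- matrix(rnorm(40), 20, 2)
  train <- matrix(rnorm(8), 4, 2)
  clf <- mock_logreg(c(0.5, 0.5))
  sel <- rank_batch(clf, pool, train, 5, scores_log = TRUE)
  log <- attr(sel, "log")
  expect_s3_class(log, "data.frame")
  expect_equal(nrow(log), 5 * 20)
  live <- is.finite(log$final)
  expect_true(all(log$final[live] >= 0 & log$final[live] <= 1))
  expect_true(all(log$uncertainty >= 0 & log$uncertainty <= 0.5))
  expect_true(all(log$similarity > 0 & log$similarity <= 1))
  expect_equal(sum(log$selected), 5)
})
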