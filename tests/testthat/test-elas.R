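fast_logreg <- function() learner_spec("logreg_l2", grid = data.frame(C = 1))

test_that("stratified internal folds partition with balanced class shares", {
  y <- c(rep(1L, 10), rep(0L, 90))
  folds <- make_internal_folds(y, 5, seed = 4)
  val_sizes <- vapply(folds, function(f) length(f$internal_val), integer(1))
  expect_equal(val_sizes, rep(20L, 5))
  pos_per_fold <- vapply(folds, function(f) sum(y[f$internal_val]), integer(1))
  expect_equal(pos_per_fold, rep(2L, 5))
  all_val <- sort(unlist(lapply(folds, `[[`, "internal_val")))
  expect_identical(all_val, 1:100) # union = everything, no duplicates
  for (f in folds) {
    expect_length(intersect(f$pool, f$internal_val), 0)
  }
  expect_error(make_internal_folds(c(rep(1, 3), rep(0, 50)), 5),
               "at least n_folds")
})

test_that("fold class proportions stay within one sample of global", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(40:300, 1)
    y <- rbinom(n, 1, runif(1, 0.1, 0.5))
    k <- sample(2:5, 1)
    if (min(table(y)) < k) next
    folds <- make_internal_folds(y, k, seed = rep)
    for (cls in 0:1) {
      per_fold <- vapply(folds, function(f) sum(y[f$internal_val] == cls),
                         integer(1))
      expect_lte(diff(range(per_fold)), 1)
    }
  }
})

test_that("balanced seeds draw n_seed/2 per class without replacement", {
  y <- c(rep(1L, 40), rep(0L, 160))
  idx <- draw_balanced_seed(y, 50, seed = 8)
  expect_length(idx, 50)
  expect_length(unique(idx), 50)
  expect_equal(sum(y[idx]), 25L)
  expect_error(draw_balanced_seed(y, 51), "even")
  expect_error(draw_balanced_seed(c(rep(1L, 20), rep(0L, 100)), 50),
               "minority")
})

test_that("active sampling obeys the record-count law and training-size ladder", {
  set.seed(6)
  cfg <- elas_config(n_seed = 20, n_batch = 10, t_seed = 1, k = 1,
                     n_folds = 2, learner = fast_logreg())
  run_case <- function(n_pool_total) {
    X <- matrix(rnorm(n_pool_total * 3), ncol = 3)
    y <- rep(c(0L, 1L), length.out = n_pool_total)
    seed_local <- draw_balanced_seed(y, cfg$n_seed, seed = 1)
    run <- active_sampling_run(X, y, setdiff(seq_len(n_pool_total), seed_local),
                               seed_local, list(C = 1), cfg, trace = TRUE)
    run
  }
  run <- run_case(120)
  expect_length(run, floor((120 - 20) / 10) + 1) # 11 records
  n_train <- vapply(run, `[[`, integer(1), "n_train")
  expect_equal(n_train, 20L + 10L * (seq_along(run) - 1L))

  # 5 short of a full final batch -> the short remainder is never queried
  expect_length(run_case(125), 11)
  # seed swallows the whole pool -> a single classifier on everything
  expect_length(run_case(20), 1)
})

test_that("pool/train disjointness and conservation hold at every iteration", {
  set.seed(30)
  X <- matrix(rnorm(90 * 3), 90, 3)
  y <- rep(c(0L, 1L), length.out = 90)
  cfg <- elas_config(n_seed = 10, n_batch = 10, t_seed = 1, k = 1,
                     n_folds = 2, learner = fast_logreg())
  seed_local <- draw_balanced_seed(y, 10, seed = 2)
  pool0 <- setdiff(seq_len(90), seed_local)
  run <- active_sampling_run(X, y, pool0, seed_local, list(C = 1), cfg,
                             trace = TRUE)
  snaps <- attr(run, "trace")
  for (s in snaps) {
    expect_length(intersect(s$pool, s$train_data), 0)
    expect_equal(sort(c(s$pool, s$train_data)), seq_len(90))
  }
  expect_error(active_sampling_run(X, y, pool0, c(seed_local, pool0[1]),
                                   list(C = 1), cfg),
               "disjoint")
})

test_that("select_top_k agrees with a brute-force (score, iteration) sort", {
  set.seed(14)
  X_val <- matrix(rnorm(60 * 2), 60, 2)
  y_val <- rep(c(0L, 1L), 30)
  records <- lapply(1:8, function(i) {
    list(classifier = mock_logreg(rnorm(2)), iteration = i,
         n_train = 10 + i, internal_val_score = NA_real_)
  })
  picked <- select_top_k(records, X_val, y_val, k = 4, metric = "auroc")
  scores <- vapply(records, function(r) {
    auroc(predict_proba(r$classifier, X_val)[, "p_positive"], y_val)
  }, numeric(1))
  ord <- order(-scores, seq_along(records))
  expect_equal(vapply(picked, `[[`, integer(1), "iteration"), ord[1:4])
  expect_equal(vapply(picked, `[[`, numeric(1), "internal_val_score"),
               scores[ord[1:4]])

  # identical members -> first k by iteration
  same <- lapply(1:5, function(i) {
    list(classifier = mock_logreg(c(1, 1)), iteration = i, n_train = 10 + i)
  })
  first2 <- select_top_k(same, X_val, y_val, k = 2)
  expect_equal(vapply(first2, `[[`, integer(1), "iteration"), 1:2)
  # k = 1 -> the argmax record
  expect_equal(select_top_k(records, X_val, y_val, 1)[[1]]$iteration,
               which.max(scores))

  expect_error(select_top_k(records, X_val, y_val, 99), "exceeds")
  expect_error(select_top_k(records, X_val, rep(1L, 60), 2), "both classes")
})

test_that("fit_elas assembles n_folds x t_seed x k members and reproduces", {
  spec <- sim_spec(n = 200, prevalence = 0.3, seed = 77)
  co <- generate_cohort(spec)
  st <- fit_preprocess(co)
  X <- apply_preprocess(co, st)
  cfg <- elas_config(n_seed = 10, n_batch = 20, t_seed = 1, k = 2,
                     n_folds = 2, learner = fast_logreg(), master_seed = 5)
  m1 <- fit_elas(X, co$labels, cfg, preprocess = st)
  expect_s3_class(m1, "elas_model")
  expect_length(m1$members, 2 * 1 * 2)
  scores1 <- vapply(m1$members, `[[`, numeric(1), "internal_val_score")

  m2 <- fit_elas(X, co$labels, cfg, preprocess = st)
  expect_equal(scores1, vapply(m2$members, `[[`, numeric(1),
                               "internal_val_score"))
  expect_equal(predict_proba(m1, X), predict_proba(m2, X))

  # a different master seed changes the runs
  cfg2 <- cfg
  cfg2$master_seed <- 6L
  m3 <- fit_elas(X, co$labels, cfg2)
  expect_false(identical(predict_proba(m1, X), predict_proba(m3, X)))

  # prediction straight from the cohort through the stored preprocess state
  expect_equal(predict_proba(m1, co), predict_proba(m1, X))
})

test_that("infeasible configurations fail fast with the stated constraints", {
  y <- c(rep(1L, 30), rep(0L, 170))
  X <- matrix(rnorm(200 * 2), 200, 2)
  # n_seed/2 beyond the pool minority class
  cfg_seed <- elas_config(n_seed = 60, n_batch = 10, t_seed = 1, k = 1,
                          n_folds = 2, learner = fast_logreg())
  expect_error(fit_elas(X, y, cfg_seed), "minority")
  # k beyond the record count a pool can yield
  cfg_k <- elas_config(n_seed = 20, n_batch = 10, t_seed = 1, k = 50,
                       n_folds = 2, learner = fast_logreg())
  expect_error(fit_elas(X, y, cfg_k), "base classifiers")
  expect_error(elas_config(n_seed = 51), "even")
})

test_that("ensemble prediction is the member mean: convexity and symmetry", {
  base <- list(classifier = mock_logreg(c(2, -1)), iteration = 1L,
               n_train = 10L, internal_val_score = 0.5)
  mk <- function(beta) {
    r <- base
    r$classifier <- mock_logreg(beta)
    r
  }
  members <- list(mk(c(2, -1)), mk(c(-1, 1)), mk(c(0.5, 0)))
  model <- structure(
    list(members = members, config = elas_config(learner = fast_logreg()),
         params = list(C = 1), center = c(0, 0), scale = c(1, 1),
         preprocess = NULL, n_features = 2L, version = 1L),
    class = "elas_model"
  )
  X <- matrix(rnorm(40), 20, 2)
  p <- predict_proba(model, X)
  expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-9)
  per_member <- vapply(members, function(m) {
    predict_proba(m$classifier, X)[, "p_positive"]
  }, numeric(20))
  expect_equal(p[, "p_positive"], rowMeans(per_member), tolerance = 1e-12)
  expect_true(all(p[, "p_positive"] >= apply(per_member, 1, min) - 1e-12))
  expect_true(all(p[, "p_positive"] <= apply(per_member, 1, max) + 1e-12))
  # permutation invariance in the member list
  model_rev <- model
  model_rev$members <- rev(members)
  expect_equal(predict_proba(model_rev, X), p, tolerance = 1e-12)

  # two members emitting 0.6 and 0.2 -> ensemble 0.4
  m2 <- model
  m2$members <- list(mk(c(0, 0)), mk(c(0, 0)))
  m2$members[[1]]$classifier$intercept <- qlogis(0.6)
  m2$members[[1]]$classifier$beta <- c(0, 0)
  m2$members[[2]]$classifier$intercept <- qlogis(0.2)
  m2$members[[2]]$classifier$beta <- c(0, 0)
  expect_equal(unname(predict_proba(m2, X)[, "p_positive"]),
               rep(0.4, 20), tolerance = 1e-12)
})

test_that("single-split internal validation mode works behind its flag", {
  spec <- sim_spec(n = 150, prevalence = 0.3, seed = 13)
  co <- generate_cohort(spec)
  X <- apply_preprocess(co, fit_preprocess(co))
  cfg <- elas_config(n_seed = 10, n_batch = 20, t_seed = 2, k = 2,
                     n_folds = 2, internal_split = "single",
                     learner = fast_logreg(), master_seed = 3)
  m <- fit_elas(X, co$labels, cfg)
  expect_length(m$members, 2 * 2) # t_seed x k, one split
})

test_that("model JSON archive round-trips predictions for every family", {
  spec <- sim_spec(n = 120, prevalence = 0.35, seed = 10, n_continuous = 2,
                   n_categorical = 2, n_informative = 3)
  co <- generate_cohort(spec)
  st <- fit_preprocess(co)
  X <- apply_preprocess(co, st)
  for (fam in c("svm_rbf", "logreg_l2", "cart")) {
    grid <- default_first_row <- learner_spec(fam)$grid[1, , drop = FALSE]
    cfg <- elas_config(n_seed = 10, n_batch = 20, t_seed = 1, k = 1,
                       n_folds = 2, master_seed = 2,
                       learner = learner_spec(fam, grid = grid))
    m <- fit_elas(X, co$labels, cfg, preprocess = st)
    path <- withr::local_tempfile(fileext = ".json")
    save_elas(m, path)
    m2 <- load_elas(path)
    expect_equal(predict_proba(m2, X), predict_proba(m, X),
                 tolerance = 1e-12)
    expect_equal(predict_proba(m2, co), predict_proba(m, co),
                 tolerance = 1e-12)
    expect_equal(m2$params, m$params, ignore_attr = TRUE)
  }
})

test_that("record-count law holds over random triples vs loop simulation", {
  # direct loop simulation as the independent oracle for the closed formula
  simulate_loop <- function(n_pool_total, n_seed, n_batch) {
    pool <- n_pool_total - n_seed
    records <- 1L
    while (pool >= n_batch) {
      pool <- pool - n_batch
      records <- records + 1L
    }
    records
  }
  set.seed(500)
  for (i in 1:500) {
    n_total <- sample(10:5000, 1)
    n_seed <- 2 * sample(1:(n_total %/% 2), 1)
    n_batch <- sample(1:50, 1)
    expect_identical(
      floor((n_total - n_seed) / n_batch) + 1,
      as.double(simulate_loop(n_total, n_seed, n_batch))
    )
  }
})
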