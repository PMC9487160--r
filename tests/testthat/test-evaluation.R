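eval_fixture <- function(n = 260, prevalence = 0.25, seed = 31) {
  co <- generate_cohort(sim_spec(n = n, prevalence = prevalence, seed = seed,
                                 effect_size = 1.2))
  st <- fit_preprocess(co)
  list(X = apply_preprocess(co, st), y = co$labels)
}

test_that("run_baselines fits supported roster names behind one contract", {
  d <- eval_fixture(n = 150)
  fits <- run_baselines(d$X, d$y, c("base_logreg", "base_cart"),
                        seed = 3, grid = NULL)
  expect_named(fits, c("base_logreg", "base_cart"))
  for (f in fits) {
    p <- predict_proba(f, d$X)
    expect_equal(dim(p), c(150, 2))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
  }
  expect_error(run_baselines(d$X, d$y, "gradient_unicorn"), "unknown roster")
})

test_that("unavailable published baselines raise the structured condition", {
  d <- eval_fixture(n = 100)
  for (nm in c("adaboost", "bagging", "smote+svm", "tomeklinks+svm")) {
    expect_error(run_baselines(d$X, d$y, nm),
                 class = "elas_baseline_unavailable")
  }
})

test_that("repeated_holdout aggregates per-repeat metrics deterministically", {
  d <- eval_fixture()
  grid1 <- data.frame(C = 1)
  rep1 <- repeated_holdout(d$X, d$y, list(
    roster_method("base_logreg", grid = grid1)
  ), n_repeats = 3, master_seed = 7)
  expect_s3_class(rep1, "elas_eval_report")
  expect_equal(nrow(rep1$per_repeat), 3)
  expect_equal(unique(rep1$summary$n_repeats), 3)
  # mean/SD recomputed from stored per-repeat values match the summary
  for (metric in c("auroc", "auprc", "sensitivity", "specificity")) {
    v <- rep1$per_repeat[[metric]]
    srow <- rep1$summary[rep1$summary$metric == metric, ]
    expect_equal(srow$mean, mean(v))
    expect_equal(srow$sd, sd(v))
  }
  # one method -> no t-tests
  expect_null(rep1$t_tests)

  # determinism under the master seed
  rep1b <- repeated_holdout(d$X, d$y, list(
    roster_method("base_logreg", grid = grid1)
  ), n_repeats = 3, master_seed = 7)
  expect_equal(rep1$per_repeat, rep1b$per_repeat)

  # two identical methods -> identical metric columns, degenerate t-tests
  twin <- list(roster_method("base_logreg", grid = grid1),
               elas_method("base_logreg_copy", function(X, y, seed) {
                 spec <- learner_spec("logreg_l2", grid = grid1)
                 fit_base(spec, list(C = 1), X, y, seed = seed)
               }))
  rep2 <- repeated_holdout(d$X, d$y, twin, n_repeats = 3, master_seed = 7)
  a <- rep2$per_repeat[rep2$per_repeat$method == "base_logreg", "auroc"]
  b <- rep2$per_repeat[rep2$per_repeat$method == "base_logreg_copy", "auroc"]
  expect_equal(a, b)
  expect_s3_class(rep2$t_tests, "data.frame")
  expect_true(all(rep2$t_tests$p_value == 1))
})

test_that("a failing method is excluded with a warning, not fatal", {
  d <- eval_fixture(n = 120)
  broken <- elas_method("broken", function(X, y, seed) stop("boom"))
  ok <- roster_method("base_logreg", grid = data.frame(C = 1))
  warns <- testthat::capture_warnings(
    rep <- repeated_holdout(d$X, d$y, list(ok, broken), n_repeats = 2,
                            master_seed = 2)
  )
  expect_true(any(grepl("failed on repeat", warns)))
  broken_rows <- rep$per_repeat[rep$per_repeat$method == "broken", ]
  expect_true(all(is.na(broken_rows$auroc)))
  expect_equal(rep$summary$n_repeats[rep$summary$method == "broken"][1], 0)
  ok_summary <- rep$summary[rep$summary$method == "base_logreg", ]
  expect_false(any(is.na(ok_summary$mean)))
})

test_that("pooled t-tests concatenate per-task pairs explicitly", {
  d1 <- eval_fixture(n = 160, seed = 41)
  d2 <- eval_fixture(n = 160, seed = 42)
  methods <- list(roster_method("base_logreg", grid = data.frame(C = 1)),
                  roster_method("base_cart",
                                grid = data.frame(max_depth = 3,
                                                  min_samples_leaf = 5)))
  r1 <- repeated_holdout(d1$X, d1$y, methods, n_repeats = 2, master_seed = 1)
  r2 <- repeated_holdout(d2$X, d2$y, methods, n_repeats = 2, master_seed = 1)
  pooled <- pooled_t_test(list(r1, r2), "base_logreg", "base_cart", "auroc")
  expect_true(is.finite(pooled$p_value))
  # pooling two tasks doubles the pairs
  expect_equal(pooled$df, 3)
})

test_that("elas slots into the harness through the estimator contract", {
  d <- eval_fixture(n = 220, prevalence = 0.3, seed = 55)
  cfg <- elas_config(n_seed = 10, n_batch = 20, t_seed = 1, k = 2,
                     n_folds = 2,
                     learner = learner_spec("logreg_l2",
                                            grid = data.frame(C = 1)))
  rep <- repeated_holdout(d$X, d$y, c("elas", "base_logreg"),
                          n_repeats = 2, master_seed = 11,
                          grid = data.frame(C = 1), elas_cfg = cfg)
  expect_setequal(unique(rep$per_repeat$method), c("elas", "base_logreg"))
  expect_true(all(is.finite(rep$per_repeat$auroc)))
})
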