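#' Configuration for ensemble learning with active sampling
#'
#' Bundles every tunable of the meta-classifier. Defaults follow the
#' reference protocol: batches of 10 queried samples, 3 seed initializations
#' per internal-validation fold, top 20 classifiers kept per run, stratified
#' 5-fold internal validation.
#'
#' @param n_seed Size of the balanced initial training seed (even;
#'   `n_seed/2` drawn from each class). Default 50.
#' @param n_batch Samples queried per active-sampling round. Default 10.
#' @param t_seed Independent balanced-seed initializations per fold.
#'   Default 3.
#' @param k Top-scoring base classifiers kept per (fold x seed) run.
#'   Default 20.
#' @param n_folds Stratified internal-validation folds. Default 5.
#' @param learner A [learner_spec()]. Default L2 logistic regression.
#' @param selection_metric Metric ranking base classifiers on the internal
#'   validation fold: `"auroc"` (default) or `"auprc"`.
#' @param alpha_convention,similarity_map,alpha_update Ranked batch-mode
#'   sampling conventions; see [rank_batch()].
#' @param internal_split `"cv"` (default) uses the stratified fold scheme;
#'   `"single"` uses one random stratified 20% internal-validation split
#'   (the simpler scheme the fold mechanism supersedes), giving
#'   `t_seed * k` members.
#' @param tune_folds Folds for the one-off hyperparameter grid search
#'   (default 5; skipped when the grid has a single row).
#' @param master_seed Integer master seed; all randomness (folds, seeds,
#'   backend fits) is derived from it through a fixed spawning scheme.
#' @return An object of class `elas_config`.
#' @export
elas_config <- function(n_seed = 50, n_batch = 10, t_seed = 3, k = 20,
                        n_folds = 5, learner = learner_spec("logreg_l2"),
                        selection_metric = c("auroc", "auprc"),
                        alpha_convention = c("diversity_first", "literal"),
                        similarity_map = c("inverse", "exp"),
                        alpha_update = c("per_pick", "frozen"),
                        internal_split = c("cv", "single"),
                        tune_folds = 5, master_seed = 1L) {
  selection_metric <- match.arg(selection_metric)
  alpha_convention <- match.arg(alpha_convention)
  similarity_map <- match.arg(similarity_map)
  alpha_update <- match.arg(alpha_update)
  internal_split <- match.arg(internal_split)
  stopifnot(inherits(learner, "elas_learner_spec"))
  if (n_seed < 2 || n_seed %% 2 != 0) stop("n_seed must be an even count >= 2")
  if (n_batch < 1) stop("n_batch must be >= 1")
  if (t_seed < 1 || k < 1 || n_folds < 2) {
    stop("t_seed >= 1, k >= 1 and n_folds >= 2 are required")
  }
  structure(
    list(n_seed = as.integer(n_seed), n_batch = as.integer(n_batch),
         t_seed = as.integer(t_seed), k = as.integer(k),
         n_folds = as.integer(n_folds), learner = learner,
         selection_metric = selection_metric,
         alpha_convention = alpha_convention,
         similarity_map = similarity_map, alpha_update = alpha_update,
         internal_split = internal_split,
         tune_folds = as.integer(tune_folds),
         master_seed = as.integer(master_seed)),
    class = "elas_config"
  )
}

# deterministic stream spawning: one integer seed per (fold, t_seed) run,
# bounded below 2^31 for R's 32-bit set.seed
spawn_seed <- function(master_seed, fold, t) {
  as.integer((abs(as.numeric(master_seed)) %% 100000) * 16384 +
               fold * 128 + t)
}

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(as.integer(seed))
  expr
}

#' Stratified internal-validation folds
#'
#' Partitions the sample indices into `n_folds` folds preserving class
#' proportions to within one sample, so that every sample serves exactly once
#' as internal-validation material. Returns, for each fold, the fold itself
#' (`internal_val`) and its complement (`pool`), the material active sampling
#' may draw from.
#'
#' @param y Binary labels (each class needs at least `n_folds` members).
#' @param n_folds Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return List of `n_folds` lists with integer `pool` and `internal_val`.
#' @export
make_internal_folds <- function(y, n_folds, seed = 1L) {
  y <- check_binary_labels(y, length(y))
  n <- length(y)
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < n_folds)) {
    stop("each class needs at least n_folds members for stratified folds")
  }
  fold_id <- integer(n)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  lapply(seq_len(n_folds), function(f) {
    list(pool = which(fold_id != f), internal_val = which(fold_id == f))
  })
}

#' Draw a balanced initial training seed
#'
#' Samples `n_seed/2` indices without replacement from each class of the
#' training pool, yielding the balanced seed that initializes the first base
#' classifier. The caller removes the drawn indices from the pool.
#'
#' @param pool_labels Binary labels of the pool rows.
#' @param n_seed Even seed size; `n_seed/2` must not exceed the minority
#'   class size.
#' @param seed Optional integer seed; by default the current RNG state is
#'   used (callers inside [fit_elas()] manage seeding).
#' @return Integer indices into `pool_labels`, positives first.
#' @export
draw_balanced_seed <- function(pool_labels, n_seed, seed = NULL) {
  pool_labels <- check_binary_labels(pool_labels, length(pool_labels))
  if (n_seed %% 2 != 0) stop("n_seed must be even (n_seed/2 per class)")
  half <- n_seed / 2
  pos <- which(pool_labels == 1)
  neg <- which(pool_labels == 0)
  if (length(pos) < half || length(neg) < half) {
    stop(sprintf(
      "n_seed/2 = %d exceeds a class size in the pool (pos %d, neg %d); the balanced-seed constraint requires n_seed/2 <= minority class size",
      half, length(pos), length(neg)
    ))
  }
  draw <- function() c(pos[sample.int(length(pos), half)],
                       neg[sample.int(length(neg), half)])
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' One active-sampling run
#'
#' Starting from the balanced seed, repeatedly: fit a base classifier on the
#' current training data, then (while at least `n_batch` samples remain in
#' the pool) query the `n_batch` highest-ranked pool samples with ranked
#' batch-mode sampling, move them (with their true labels) into the training
#' data, and continue. No early-stopping criterion is applied; the run ends
#' when the pool cannot supply another full batch, and the classifier fitted
#' last is the final record. For a pool of size `N_trainPool` before seed
#' removal this yields exactly
#' `floor((N_trainPool - n_seed)/n_batch) + 1` records, record `i` trained
#' on `n_seed + (i-1) * n_batch` samples.
#'
#' @param X Standardized numeric feature matrix (full training set).
#' @param y Binary labels aligned with `X`.
#' @param pool_idx Integer indices of the queryable pool (seed already
#'   removed).
#' @param seed_idx Integer indices of the balanced seed.
#' @param params Named list of fixed hyperparameters for the learner.
#' @param config An [elas_config()].
#' @param trace If `TRUE`, attach per-iteration `pool`/`train_data` index
#'   snapshots as attribute `"trace"` for invariant auditing.
#' @return List of records, each with `classifier`, `iteration`, `n_train`;
#'   `internal_val_score` is filled in later by [select_top_k()].
#' @export
active_sampling_run <- function(X, y, pool_idx, seed_idx, params, config,
                                trace = FALSE) {
  stopifnot(inherits(config, "elas_config"))
  if (length(intersect(pool_idx, seed_idx)) > 0) {
    stop("pool and seed indices must be disjoint")
  }
  pool <- as.integer(pool_idx)
  train_data <- as.integer(seed_idx)
  records <- list()
  snapshots <- if (trace) list() else NULL
  iteration <- 0L
  repeat {
    iteration <- iteration + 1L
    clf <- fit_base(config$learner, params, X[train_data, , drop = FALSE],
                    y[train_data],
                    seed = spawn_seed(config$master_seed, 0L, iteration))
    records[[iteration]] <- list(classifier = clf, iteration = iteration,
                                 n_train = length(train_data),
                                 internal_val_score = NA_real_)
    if (trace) {
      snapshots[[iteration]] <- list(pool = pool, train_data = train_data)
    }
    if (length(pool) < config$n_batch) break
    sel <- rank_batch(clf, X[pool, , drop = FALSE],
                      X[train_data, , drop = FALSE], config$n_batch,
                      alpha_convention = config$alpha_convention,
                      similarity_map = config$similarity_map,
                      alpha_update = config$alpha_update)
    train_data <- c(train_data, pool[sel])
    pool <- pool[-sel]
  }
  if (trace) attr(records, "trace") <- snapshots
  records
}

#' Select the top-K base classifiers on an internal-validation fold
#'
#' Scores every record's classifier on the held-out internal-validation fold
#' and keeps the `k` best; ties break towards the earlier iteration, i.e.
#' the smaller (more balanced) training set.
#'
#' @param records Output of [active_sampling_run()].
#' @param X_val,y_val The internal-validation fold (both classes required).
#' @param k Number of records to keep (`k <= length(records)`).
#' @param metric `"auroc"`, `"auprc"`, or a scorer function.
#' @return The `k` selected records with `internal_val_score` filled in,
#'   ordered best-first.
#' @export
select_top_k <- function(records, X_val, y_val, k, metric = "auroc") {
  if (k > length(records)) {
    stop(sprintf(
      "k = %d exceeds the %d base classifiers this run produced; keep k <= floor((N_trainPool - n_seed)/n_batch) + 1",
      k, length(records)
    ))
  }
  scorer <- resolve_metric(metric)
  y_val <- check_binary_labels(y_val, nrow(X_val))
  if (length(unique(y_val)) < 2) {
    stop("internal validation fold must contain both classes")
  }
  scores <- vapply(records, function(rec) {
    scorer(predict_proba(rec$classifier, X_val)[, "p_positive"], y_val)
  }, numeric(1))
  iters <- vapply(records, `[[`, integer(1), "iteration")
  ord <- order(-scores, iters)
  selected <- records[ord[seq_len(k)]]
  for (i in seq_along(selected)) {
    selected[[i]]$internal_val_score <- scores[ord[i]]
  }
  selected
}

resolve_metric <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(metric, auroc = auroc, auprc = auprc,
         stop("unknown metric: ", metric))
}

#' Fit the ensemble-with-active-sampling meta-classifier
#'
#' The full training algorithm: hyperparameters are tuned once by grid
#' search on the whole training set and frozen; the training set is split
#' into stratified internal-validation folds; for every fold and every one
#' of `t_seed` balanced-seed initializations an active-sampling run grows a
#' list of base classifiers, of which the `k` best on that fold's
#' internal-validation set are kept; the `n_folds * t_seed * k` selected
#' members predict by unweighted probability averaging.
#'
#' Feature columns are standardized internally (center/scale stored on the
#' model) so that the Euclidean query distances and the SVM kernel are
#' scale-free.
#'
#' @param X Numeric feature matrix (e.g. from [apply_preprocess()]).
#' @param y Binary labels.
#' @param config An [elas_config()].
#' @param preprocess Optional `elas_preprocess` carried on the model so the
#'   ensemble can predict straight from cohorts.
#' @param trace If `TRUE`, keep per-run iteration snapshots in
#'   `model$trace`.
#' @return An object of class `elas_model`.
#' @export
fit_elas <- function(X, y, config = elas_config(), preprocess = NULL,
                     trace = FALSE) {
  stopifnot(inherits(config, "elas_config"))
  X <- as.matrix(X)
  y <- check_binary_labels(y, nrow(X))

  center <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  scale <- ifelse(sds > 0, sds, 1)
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")

  # one-off hyperparameter selection, frozen for every base classifier
  tuned <- if (nrow(config$learner$grid) > 1L) {
    tune(config$learner, Xs, y, n_folds = config$tune_folds,
         metric = resolve_metric(config$selection_metric),
         seed = spawn_seed(config$master_seed, 0L, 0L))
  } else {
    list(params = as.list(config$learner$grid[1L, , drop = FALSE]),
         cv_score = NA_real_, grid_scores = NA_real_)
  }

  folds <- if (config$internal_split == "cv") {
    make_internal_folds(y, config$n_folds,
                        seed = spawn_seed(config$master_seed, 0L, 0L))
  } else {
    single_internal_split(y, val_fraction = 0.2,
                          seed = spawn_seed(config$master_seed, 0L, 0L))
  }

  validate_elas_feasibility(y, folds, config)

  members <- list()
  traces <- if (trace) list() else NULL
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    for (t in seq_len(config$t_seed)) {
      run_seed <- spawn_seed(config$master_seed, f, t)
      run <- with_seed(run_seed, {
        seed_local <- draw_balanced_seed(y[fold$pool], config$n_seed)
        seed_idx <- fold$pool[seed_local]
        pool_idx <- fold$pool[-seed_local]
        active_sampling_run(Xs, y, pool_idx, seed_idx, tuned$params, config,
                            trace = trace)
      })
      if (trace) traces[[sprintf("fold%d_seed%d", f, t)]] <- attr(run, "trace")
      picked <- select_top_k(run, Xs[fold$internal_val, , drop = FALSE],
                             y[fold$internal_val], config$k,
                             metric = config$selection_metric)
      for (i in seq_along(picked)) {
        picked[[i]]$fold <- f
        picked[[i]]$t_seed <- t
      }
      members <- c(members, picked)
    }
  }

  structure(
    list(members = members, config = config, params = tuned$params,
         tuning = tuned[c("cv_score", "grid_scores")],
         center = center, scale = scale,
         preprocess = preprocess, trace = traces,
         n_features = ncol(X), version = 1L),
    class = "elas_model"
  )
}

# stratified single split used by internal_split = "single"
single_internal_split <- function(y, val_fraction, seed) {
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      n_val <- round(length(idx) * val_fraction)
      take <- idx[sample.int(length(idx), n_val)]
      fold_id[take] <- 1L
    }
  })
  list(list(pool = which(fold_id == 0L), internal_val = which(fold_id == 1L)))
}

validate_elas_feasibility <- function(y, folds, config) {
  for (fold in folds) {
    pool_y <- y[fold$pool]
    minority <- min(sum(pool_y == 1), sum(pool_y == 0))
    if (config$n_seed / 2 > minority) {
      stop(sprintf(
        "n_seed/2 = %d exceeds the minority-class size %d of a training pool",
        config$n_seed / 2, minority
      ))
    }
    n_records <- floor((length(fold$pool) - config$n_seed) / config$n_batch) + 1
    if (config$k > n_records) {
      stop(sprintf(
        "k = %d exceeds the %d base classifiers a pool of %d samples yields (n_seed %d, n_batch %d)",
        config$k, n_records, length(fold$pool), config$n_seed, config$n_batch
      ))
    }
    if (length(unique(y[fold$internal_val])) < 2) {
      stop("an internal-validation fold contains a single class")
    }
  }
  invisible(TRUE)
}

#' @export
print.elas_model <- function(x, ...) {
  cat(sprintf(
    "<elas_model> %d members (%s), %d folds x %d seeds x top %d\n",
    length(x$members), x$config$learner$family, x$config$n_folds,
    x$config$t_seed, x$config$k
  ))
  cat(sprintf("  frozen hyperparameters: %s\n",
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @describeIn fit_elas Averaged class probabilities of the ensemble: the
#'   unweighted mean of every member's probability rows. Accepts a numeric
#'   matrix on the training column space, or (when the model carries a
#'   preprocessing state) an `elas_cohort`/`data.frame`.
#' @param object An `elas_model`.
#' @param ... Unused.
#' @export
predict_proba.elas_model <- function(object, X, ...) {
  X <- resolve_model_input(object, X)
  Xs <- sweep(sweep(X, 2L, object$center, "-"), 2L, object$scale, "/")
  acc <- matrix(0, nrow(Xs), 2L)
  for (m in object$members) {
    acc <- acc + predict_proba(m$classifier, Xs)
  }
  out <- acc / length(object$members)
  colnames(out) <- c("p_negative", "p_positive")
  out
}

resolve_model_input <- function(object, X) {
  if (inherits(X, "elas_cohort") || is.data.frame(X)) {
    if (is.null(object$preprocess)) {
      stop("model carries no preprocessing state; supply a numeric matrix")
    }
    X <- apply_preprocess(X, object$preprocess)
  }
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop(sprintf("expected %d feature columns, got %d",
                 object$n_features, ncol(X)))
  }
  X
}

#' @describeIn fit_elas Class prediction at a probability threshold
#'   (default 0.5).
#' @param newdata Feature input as in `predict_proba`.
#' @param threshold Positive-call threshold.
#' @export
predict.elas_model <- function(object, newdata, threshold = 0.5, ...) {
  as.integer(predict_proba(object, newdata)[, "p_positive"] >= threshold)
}
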