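#' Build an evaluation method from the estimator contract
#'
#' An evaluation method is a named fit recipe: `fit(X, y, seed)` must return
#' an object implementing [predict_proba()]. [repeated_holdout()] and
#' [run_baselines()] consume lists of these.
#'
#' @param name Display name.
#' @param fit Function `(X, y, seed)` returning a fitted model.
#' @return An object of class `elas_method`.
#' @export
elas_method <- function(name, fit) {
  stopifnot(is.character(name), is.function(fit))
  structure(list(name = name, fit = fit), class = "elas_method")
}

#' Standard method roster entries
#'
#' Translates roster names into [elas_method()] recipes. Supported:
#' `base_svm`, `base_logreg`, `base_cart` (a single grid-search-tuned base
#' learner fitted on the full, imbalanced training split) and `elas`
#' (the ensemble meta-classifier). The published comparison algorithms
#' (`adaboost`, `bagging`, `smote+<learner>`, `tomeklinks+<learner>`) must
#' be delegated to established implementations, none of which exist in this
#' offline R environment, so those names raise a structured
#' `elas_baseline_unavailable` error rather than a bespoke re-implementation.
#'
#' @param name Roster name.
#' @param grid Optional learner grid override for the `base_*` entries.
#' @param tune_folds CV folds for the one-off grid search (default 5).
#' @param elas_cfg An [elas_config()] used by the `elas` entry (its
#'   `master_seed` is overridden by the per-fit seed).
#' @return An [elas_method()].
#' @export
roster_method <- function(name, grid = NULL, tune_folds = 5,
                          elas_cfg = elas_config()) {
  base_families <- c(base_svm = "svm_rbf", base_logreg = "logreg_l2",
                     base_cart = "cart")
  if (name %in% names(base_families)) {
    family <- base_families[[name]]
    return(elas_method(name, function(X, y, seed) {
      spec <- learner_spec(family, grid = grid)
      params <- if (nrow(spec$grid) > 1L) {
        tune(spec, X, y, n_folds = tune_folds, seed = seed)$params
      } else {
        as.list(spec$grid[1L, , drop = FALSE])
      }
      fit_base(spec, params, X, y, seed = seed)
    }))
  }
  if (name == "elas") {
    return(elas_method(name, function(X, y, seed) {
      cfg <- elas_cfg
      cfg$master_seed <- as.integer(seed)
      fit_elas(X, y, cfg)
    }))
  }
  if (grepl("^(adaboost|bagging|smote|tomeklinks)", name)) {
    stop(structure(
      class = c("elas_baseline_unavailable", "error", "condition"),
      list(message = paste0(
        "baseline '", name, "' requires an established external ",
        "implementation that is not available in this environment"
      ), call = NULL)
    ))
  }
  stop("unknown roster name: ", name)
}

#' Fit every roster method on a training set
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @param roster Character vector of roster names (see [roster_method()]) or
#'   a list of [elas_method()] objects.
#' @param seed Integer seed shared by every fit.
#' @param ... Passed to [roster_method()] for character rosters.
#' @return Named list of fitted models implementing [predict_proba()].
#' @export
run_baselines <- function(X, y, roster, seed = 1L, ...) {
  methods <- resolve_roster(roster, ...)
  fits <- lapply(methods, function(m) m$fit(as.matrix(X), y, seed))
  names(fits) <- vapply(methods, `[[`, character(1), "name")
  fits
}

resolve_roster <- function(roster, ...) {
  if (is.character(roster)) {
    lapply(roster, roster_method, ...)
  } else {
    lapply(roster, function(m) {
      stopifnot(inherits(m, "elas_method"))
      m
    })
  }
}

#' Repeated stratified holdout evaluation
#'
#' The published protocol: the cohort is split into a stratified 80/20
#' train/test partition, every method is fitted on the same training split
#' and scored on the same test split, and the whole process is repeated with
#' different random seeds. Reports per-repeat AUROC, AUPRC, sensitivity and
#' specificity, their means and SDs, and two-sided paired t-tests between
#' every method pair (pairing by repeat).
#'
#' A method that fails on a repeat is recorded as `NA` for that repeat with
#' a warning and excluded from its own aggregates; t-tests use complete
#' pairs only.
#'
#' @inheritParams run_baselines
#' @param n_repeats Number of repeats (default 10).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param master_seed Master seed; repeat `r` uses a derived seed.
#' @param threshold Positive-call threshold for sensitivity/specificity.
#' @return An object of class `elas_eval_report` with `per_repeat`
#'   (long-format `data.frame`), `summary`, `t_tests` and `repeat_seeds`.
#' @export
repeated_holdout <- function(X, y, roster, n_repeats = 10,
                             test_fraction = 0.2, master_seed = 1L,
                             threshold = 0.5, ...) {
  methods <- resolve_roster(roster, ...)
  method_names <- vapply(methods, `[[`, character(1), "name")
  X <- as.matrix(X)
  y <- check_binary_labels(y, nrow(X))
  repeat_seeds <- vapply(seq_len(n_repeats), function(r) {
    spawn_seed(master_seed, r, 0L)
  }, integer(1))

  rows <- list()
  for (r in seq_len(n_repeats)) {
    split <- single_internal_split(y, val_fraction = test_fraction,
                                   seed = repeat_seeds[r])[[1]]
    tr <- split$pool
    te <- split$internal_val
    for (m in seq_along(methods)) {
      res <- tryCatch({
        fit <- methods[[m]]$fit(X[tr, , drop = FALSE], y[tr], repeat_seeds[r])
        p <- predict_proba(fit, X[te, , drop = FALSE])[, "p_positive"]
        ss <- sens_spec(p, y[te], threshold)
        c(auroc = auroc(p, y[te]), auprc = auprc(p, y[te]),
          ss["sensitivity"], ss["specificity"])
      }, error = function(e) {
        warning(sprintf("method '%s' failed on repeat %d: %s",
                        method_names[m], r, conditionMessage(e)))
        c(auroc = NA_real_, auprc = NA_real_, sensitivity = NA_real_,
          specificity = NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, method = method_names[m],
        auroc = res[["auroc"]], auprc = res[["auprc"]],
        sensitivity = res[["sensitivity"]], specificity = res[["specificity"]]
      )
    }
  }
  per_repeat <- do.call(rbind, rows)
  metrics <- c("auroc", "auprc", "sensitivity", "specificity")

  summary_rows <- list()
  for (m in method_names) {
    sub <- per_repeat[per_repeat$method == m, , drop = FALSE]
    for (metric in metrics) {
      v <- sub[[metric]][!is.na(sub[[metric]])]
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        method = m, metric = metric, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n_repeats = length(v)
      )
    }
  }
  summary <- do.call(rbind, summary_rows)

  t_tests <- NULL
  if (length(method_names) > 1) {
    tt_rows <- list()
    pairs <- utils::combn(method_names, 2, simplify = FALSE)
    for (pr in pairs) {
      for (metric in c("auroc", "auprc")) {
        a <- per_repeat[per_repeat$method == pr[1], metric]
        b <- per_repeat[per_repeat$method == pr[2], metric]
        ok <- !is.na(a) & !is.na(b)
        res <- if (sum(ok) >= 2) {
          suppressWarnings(paired_t_test(a[ok], b[ok]))
        } else {
          list(p_value = NA_real_, significant = NA)
        }
        tt_rows[[length(tt_rows) + 1L]] <- data.frame(
          method_a = pr[1], method_b = pr[2], metric = metric,
          p_value = res$p_value, significant = res$significant,
          n_pairs = sum(ok)
        )
      }
    }
    t_tests <- do.call(rbind, tt_rows)
  }

  structure(
    list(per_repeat = per_repeat, summary = summary, t_tests = t_tests,
         repeat_seeds = repeat_seeds, threshold = threshold),
    class = "elas_eval_report"
  )
}

#' @export
print.elas_eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("<elas_eval_report> %d repeats, %d method(s)\n",
              length(x$repeat_seeds), length(unique(x$summary$method))))
  s <- x$summary
  s$mean <- round(s$mean, digits)
  s$sd <- round(s$sd, digits)
  print(s, row.names = FALSE)
  if (!is.null(x$t_tests)) {
    cat("paired t-tests (two-sided):\n")
    tt <- x$t_tests
    tt$p_value <- signif(tt$p_value, 3)
    print(tt, row.names = FALSE)
  }
  invisible(x)
}

#' Pool paired t-tests across prognostic tasks
#'
#' The published "all tasks" comparisons pair metric values across every
#' task and repeat jointly. Pooling heterogeneous tasks changes what the
#' test means (between-task differences enter the pairs), so this is an
#' explicit separate helper rather than a default.
#'
#' @param reports Named list of `elas_eval_report`s, one per task, produced
#'   with the same methods and repeat counts.
#' @param method_a,method_b The two method names to compare.
#' @param metric `"auroc"` or `"auprc"`.
#' @return A [paired_t_test()] result over the pooled pairs.
#' @export
pooled_t_test <- function(reports, method_a, method_b, metric = "auroc") {
  a <- unlist(lapply(reports, function(r) {
    r$per_repeat[r$per_repeat$method == method_a, metric]
  }))
  b <- unlist(lapply(reports, function(r) {
    r$per_repeat[r$per_repeat$method == method_b, metric]
  }))
  ok <- !is.na(a) & !is.na(b)
  paired_t_test(a[ok], b[ok])
}
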