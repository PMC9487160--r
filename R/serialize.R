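#' Save / load a fitted ensemble as a versioned JSON archive
#'
#' Every backend stores its classifier as plain numbers (support vectors and
#' dual coefficients, regression coefficients, or tree nodes), so the whole
#' model — config, frozen hyperparameters, standardization, optional
#' preprocessing state and all members — round-trips through a single
#' human-inspectable JSON document with a format-version field.
#'
#' @param model An `elas_model`.
#' @param path Output JSON path.
#' @return `save_elas()` returns `path` invisibly; `load_elas()` the
#'   restored `elas_model`.
#' @export
save_elas <- function(model, path) {
  stopifnot(inherits(model, "elas_model"))
  cfg <- unclass(model$config)
  cfg$learner <- list(family = model$config$learner$family,
                      grid = model$config$learner$grid)
  doc <- list(
    format_version = 1L,
    config = cfg,
    params = model$params,
    tuning = model$tuning,
    center = as.list(model$center),
    scale = as.list(model$scale),
    n_features = model$n_features,
    preprocess = if (!is.null(model$preprocess)) unclass(model$preprocess),
    members = lapply(model$members, function(m) {
      list(classifier = serialize_classifier(m$classifier),
           iteration = m$iteration, n_train = m$n_train,
           internal_val_score = m$internal_val_score,
           fold = m$fold %||% NA_integer_, t_seed = m$t_seed %||% NA_integer_)
    })
  )
  # digits = I(17): 17 significant digits guarantee exact double round-trips
  # (15 would perturb split thresholds that coincide with data values)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null")
  invisible(path)
}

serialize_classifier <- function(clf) {
  out <- unclass(clf)
  if (clf$family == "svm_rbf") out$sv <- apply(clf$sv, 1L, identity, simplify = FALSE)
  out
}

#' @rdname save_elas
#' @export
load_elas <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(as.integer(doc$format_version), 1L)) {
    stop("unsupported model format version: ", doc$format_version)
  }
  cfg_raw <- doc$config
  learner <- learner_spec(cfg_raw$learner$family,
                          grid = rebind_grid(cfg_raw$learner$grid))
  config <- do.call(elas_config, c(
    cfg_raw[c("n_seed", "n_batch", "t_seed", "k", "n_folds",
              "selection_metric", "alpha_convention", "similarity_map",
              "alpha_update", "internal_split", "tune_folds", "master_seed")],
    list(learner = learner)
  ))
  preprocess <- NULL
  if (!is.null(doc$preprocess)) {
    pp <- doc$preprocess
    pp$schema$categorical <- as.character(unlist(pp$schema$categorical))
    pp$schema$continuous <- as.character(unlist(pp$schema$continuous))
    pp$categorical_level_maps <- lapply(pp$categorical_level_maps,
                                        function(v) as.character(unlist(v)))
    pp$bin_edges <- lapply(pp$bin_edges, function(v) as.numeric(unlist(v)))
    for (slot in c("dropped_feature_names", "retained_columns",
                   "dropped_row_ids")) {
      pp[[slot]] <- as.character(unlist(pp[[slot]]))
    }
    pp$center <- vapply(pp$center, as.numeric, numeric(1))
    pp$scale <- vapply(pp$scale, as.numeric, numeric(1))
    preprocess <- structure(pp, class = "elas_preprocess")
  }
  params <- lapply(doc$params, function(v) if (is.null(v)) NA_real_ else v)
  members <- lapply(doc$members, function(m) {
    list(classifier = deserialize_classifier(m$classifier),
         iteration = as.integer(m$iteration), n_train = as.integer(m$n_train),
         internal_val_score = as.numeric(m$internal_val_score),
         fold = m$fold, t_seed = m$t_seed)
  })
  structure(
    list(members = members, config = config, params = params,
         tuning = doc$tuning,
         center = vapply(doc$center, as.numeric, numeric(1)),
         scale = vapply(doc$scale, as.numeric, numeric(1)),
         preprocess = preprocess, trace = NULL,
         n_features = as.integer(doc$n_features), version = 1L),
    class = "elas_model"
  )
}

rebind_grid <- function(grid) {
  as.data.frame(lapply(
    as.data.frame(do.call(rbind, lapply(grid, function(row) {
      lapply(row, function(v) if (is.null(v)) NA_real_ else v)
    }))),
    function(col) unlist(col)
  ))
}

deserialize_classifier <- function(raw) {
  family <- raw$family
  if (family == "svm_rbf") {
    clf <- list(
      family = "svm_rbf",
      sv = do.call(rbind, lapply(raw$sv, function(r) as.numeric(unlist(r)))),
      coef = as.numeric(unlist(raw$coef)),
      b = as.numeric(raw$b), gamma = as.numeric(raw$gamma),
      C = as.numeric(raw$C),
      platt_a = as.numeric(raw$platt_a), platt_b = as.numeric(raw$platt_b)
    )
    return(structure(clf, class = c("elas_svm_rbf", "elas_base")))
  }
  if (family == "logreg_l2") {
    clf <- list(family = "logreg_l2",
                intercept = as.numeric(raw$intercept),
                beta = as.numeric(unlist(raw$beta)), C = as.numeric(raw$C))
    return(structure(clf, class = c("elas_logreg_l2", "elas_base")))
  }
  if (family == "cart") {
    nodes <- lapply(raw$nodes, function(nd) {
      if (isTRUE(nd$leaf)) {
        list(leaf = TRUE, prob = as.numeric(nd$prob), n = as.integer(nd$n))
      } else {
        list(leaf = FALSE, feature = as.integer(nd$feature),
             threshold = as.numeric(nd$threshold),
             left = as.integer(nd$left), right = as.integer(nd$right),
             n = as.integer(nd$n))
      }
    })
    clf <- list(family = "cart", nodes = nodes, root = as.integer(raw$root),
                max_depth = if (is.null(raw$max_depth)) NA else raw$max_depth,
                min_samples_leaf = as.integer(raw$min_samples_leaf),
                p = as.integer(raw$p))
    return(structure(clf, class = c("elas_cart", "elas_base")))
  }
  stop("unknown classifier family in archive: ", family)
}
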