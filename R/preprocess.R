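#' Fit the clinical preprocessing state on a cohort
#'
#' Fits the feature pipeline used throughout the package: rows containing any
#' missing feature value are excluded; categorical features are expanded to
#' one-hot columns; continuous features are discretized into equal-frequency
#' (quantile) bins; post-encoding columns whose sample variance falls below
#' `variance_threshold` are dropped (this is also how constant features are
#' eliminated); finally per-column center/scale parameters are recorded so
#' that distance computations and kernel methods can operate on a
#' standardized matrix. Everything needed to reproduce the transform on
#' unseen data is stored in the returned state.
#'
#' @param x An `elas_cohort` (labels/follow-up ignored here).
#' @param variance_threshold Minimum post-encoding sample variance for a
#'   column to be retained. Default `0.01` (the "variance lower than 1%"
#'   rule applied to encoded columns).
#' @param n_bins Number of quantile bins for continuous features (default 4).
#'   Duplicate quantiles collapse, so a feature may end up with fewer bins.
#' @param bin_encoding `"ordinal"` (default) writes the bin index
#'   `0..n_bins-1` into a single column, so Euclidean distances respect the
#'   interval order; `"onehot"` expands bins like categorical levels.
#' @return An object of class `elas_preprocess`.
#' @export
fit_preprocess <- function(x, variance_threshold = 0.01, n_bins = 4,
                           bin_encoding = c("ordinal", "onehot")) {
  stopifnot(inherits(x, "elas_cohort"))
  bin_encoding <- match.arg(bin_encoding)
  if (nrow(x$features) < 2) stop("preprocessing requires at least 2 rows")
  feats <- x$features
  complete <- stats::complete.cases(feats)
  dropped_row_ids <- x$ids[!complete]
  feats <- feats[complete, , drop = FALSE]
  if (nrow(feats) == 0) stop("all rows contain missing values")

  level_maps <- lapply(feats[x$schema$categorical], function(v) sort(unique(v)))
  bin_edges <- lapply(feats[x$schema$continuous], function(v) {
    unname(unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1))))
  })

  state <- structure(
    list(
      version = 1L,
      schema = x$schema,
      variance_threshold = variance_threshold,
      n_bins = n_bins,
      bin_encoding = bin_encoding,
      categorical_level_maps = level_maps,
      bin_edges = bin_edges,
      dropped_feature_names = character(),
      retained_columns = character(),
      center = numeric(), scale = numeric(),
      n_fit_rows = nrow(feats),
      dropped_row_ids = dropped_row_ids
    ),
    class = "elas_preprocess"
  )

  encoded <- encode_features(feats, state)
  v <- apply(encoded, 2L, stats::var)
  state$dropped_feature_names <- colnames(encoded)[v < variance_threshold]
  state$retained_columns <- colnames(encoded)[v >= variance_threshold]
  if (length(state$retained_columns) == 0) {
    stop("variance filter dropped every encoded column")
  }
  kept <- encoded[, state$retained_columns, drop = FALSE]
  state$center <- colMeans(kept)
  sds <- apply(kept, 2L, stats::sd)
  state$scale <- ifelse(sds > 0, sds, 1)
  names(state$scale) <- names(state$center)
  state
}

# encode a feature table (no row filtering) into the full pre-drop matrix
encode_features <- function(feats, state) {
  blocks <- list()
  for (f in state$schema$categorical) {
    levels <- state$categorical_level_maps[[f]]
    block <- matrix(0, nrow(feats), length(levels),
                    dimnames = list(NULL, paste0(f, "=", levels)))
    idx <- match(feats[[f]], levels)
    unseen <- !is.na(feats[[f]]) & is.na(idx)
    if (any(unseen)) {
      warning(sprintf("feature '%s': %d unseen level value(s) mapped to an all-zero one-hot block",
                      f, sum(unseen)))
    }
    seen <- which(!is.na(idx))
    block[cbind(seen, idx[seen])] <- 1
    blocks[[f]] <- block
  }
  for (f in state$schema$continuous) {
    edges <- state$bin_edges[[f]]
    interior <- edges[-c(1L, length(edges))]
    bins <- findInterval(feats[[f]], interior) # clipped to end bins by design
    n_levels <- length(interior) + 1L
    if (state$bin_encoding == "ordinal") {
      blocks[[f]] <- matrix(bins, ncol = 1L, dimnames = list(NULL, f))
    } else {
      block <- matrix(0, nrow(feats), n_levels,
                      dimnames = list(NULL, paste0(f, "=bin", seq_len(n_levels) - 1L)))
      block[cbind(seq_len(nrow(feats)), bins + 1L)] <- 1
      blocks[[f]] <- block
    }
  }
  do.call(cbind, blocks)
}

#' Apply a fitted preprocessing state
#'
#' Transforms a cohort (or bare feature table) into the numeric matrix the
#' models consume, using only information stored at fit time: stored bin
#' edges (values outside them are clipped to the end bins), stored one-hot
#' level maps (an unseen level becomes an all-zero block, with a warning),
#' and the stored retained-column list, in order.
#'
#' @param x An `elas_cohort` or `data.frame` with the fitted feature columns.
#' @param state An `elas_preprocess` from [fit_preprocess()].
#' @param standardize If `TRUE`, also apply the stored per-column
#'   center/scale (used internally before SVM training and Euclidean
#'   similarity). Default `FALSE`, returning bin indices / indicators.
#' @return Numeric matrix, columns exactly `state$retained_columns`.
#' @export
apply_preprocess <- function(x, state, standardize = FALSE) {
  stopifnot(inherits(state, "elas_preprocess"))
  feats <- if (inherits(x, "elas_cohort")) x$features else as.data.frame(x)
  feat_cols <- c(state$schema$categorical, state$schema$continuous)
  missing_cols <- setdiff(feat_cols, names(feats))
  if (length(missing_cols) > 0) {
    stop("input lacks fitted feature column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  feats <- feats[, feat_cols, drop = FALSE]
  if (anyNA(feats)) {
    stop("missing feature values in input; rows with missing values are excluded at fit time and not imputed")
  }
  encoded <- encode_features(feats, state)
  out <- encoded[, state$retained_columns, drop = FALSE]
  if (standardize) {
    out <- sweep(out, 2L, state$center, "-")
    out <- sweep(out, 2L, state$scale, "/")
  }
  out
}

#' @export
print.elas_preprocess <- function(x, ...) {
  cat(sprintf(
    "<elas_preprocess> fit on %d rows; %d retained columns, %d dropped (var < %g); %d-bin %s binning\n",
    x$n_fit_rows, length(x$retained_columns),
    length(x$dropped_feature_names), x$variance_threshold, x$n_bins,
    x$bin_encoding
  ))
  invisible(x)
}

#' Serialize / restore a preprocessing state as versioned JSON
#'
#' @param state An `elas_preprocess`.
#' @param path JSON file path.
#' @return `write_preprocess()` returns `path` invisibly; `read_preprocess()`
#'   the restored `elas_preprocess`.
#' @export
write_preprocess <- function(state, path) {
  stopifnot(inherits(state, "elas_preprocess"))
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_preprocess
#' @export
read_preprocess <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$version) || raw$version != 1L) {
    stop("unsupported preprocess state version: ", raw$version)
  }
  raw$schema$categorical <- as.character(raw$schema$categorical %||% character())
  raw$schema$continuous <- as.character(raw$schema$continuous %||% character())
  for (slot in c("categorical_level_maps", "bin_edges")) {
    raw[[slot]] <- as.list(raw[[slot]])
  }
  raw$dropped_feature_names <- as.character(raw$dropped_feature_names %||% character())
  raw$retained_columns <- as.character(raw$retained_columns %||% character())
  raw$center <- unlist(raw$center)
  raw$scale <- unlist(raw$scale)
  raw$dropped_row_ids <- as.character(raw$dropped_row_ids %||% character())
  structure(raw, class = "elas_preprocess")
}
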