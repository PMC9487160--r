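# Classification tree with Gini impurity, honoring max_depth and
# min_samples_leaf. All feature columns are numeric (bin indices / one-hot
# indicators), so only axis-aligned numeric splits are needed. The tree is a
# flat list of nodes with integer child pointers, which serializes to JSON.
#
# Determinism: the best split minimizes the weighted child Gini impurity;
# ties break towards the lowest feature index, then the lowest threshold.
# A split must strictly reduce impurity, otherwise the node becomes a leaf.

fit_cart <- function(X, y, max_depth = NA, min_samples_leaf = 1) {
  X <- as.matrix(X)
  y <- check_binary_labels(y, nrow(X))
  if (length(unique(y)) < 2) stop("cart requires both classes in y")
  if (is.na(max_depth) || is.null(max_depth)) max_depth <- Inf
  if (max_depth < 1) stop("max_depth must be >= 1 (or NA for unlimited)")
  if (min_samples_leaf < 1) stop("min_samples_leaf must be >= 1")

  nodes <- list()
  grow <- function(rows, depth) {
    n <- length(rows)
    p_pos <- mean(y[rows])
    make_leaf <- function() {
      nodes[[length(nodes) + 1L]] <<- list(leaf = TRUE, prob = p_pos, n = n)
      length(nodes)
    }
    if (p_pos == 0 || p_pos == 1 || depth >= max_depth ||
        n < 2 * min_samples_leaf) {
      return(make_leaf())
    }
    split <- best_gini_split(X[rows, , drop = FALSE], y[rows], min_samples_leaf)
    if (is.null(split)) return(make_leaf())
    go_left <- X[rows, split$feature] <= split$threshold
    left <- grow(rows[go_left], depth + 1L)
    right <- grow(rows[!go_left], depth + 1L)
    nodes[[length(nodes) + 1L]] <<- list(
      leaf = FALSE, feature = split$feature, threshold = split$threshold,
      left = left, right = right, n = n
    )
    length(nodes)
  }
  root <- grow(seq_len(nrow(X)), 0L)
  structure(
    list(family = "cart", nodes = nodes, root = root,
         max_depth = if (is.finite(max_depth)) max_depth else NA,
         min_samples_leaf = min_samples_leaf, p = ncol(X)),
    class = c("elas_cart", "elas_base")
  )
}

# scan every feature for the impurity-minimizing binary split
best_gini_split <- function(X, y, min_samples_leaf) {
  n <- length(y)
  gini_parent <- gini_impurity(sum(y), n)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    ord <- order(xj, method = "radix")
    xs <- xj[ord]
    ys <- y[ord]
    distinct <- which(diff(xs) > 0) # split after these positions
    if (length(distinct) == 0L) next
    valid <- distinct[distinct >= min_samples_leaf &
                      (n - distinct) >= min_samples_leaf]
    if (length(valid) == 0L) next
    pos_left <- cumsum(ys)[valid]
    n_left <- valid
    imp <- (n_left * gini_impurity(pos_left, n_left) +
            (n - n_left) * gini_impurity(sum(ys) - pos_left, n - n_left)) / n
    k <- which.min(imp)
    if (imp[k] < gini_parent - 1e-12 &&
        (is.null(best) || imp[k] < best$impurity - 1e-12)) {
      cut <- valid[k]
      best <- list(feature = j,
                   threshold = (xs[cut] + xs[cut + 1L]) / 2,
                   impurity = imp[k])
    }
  }
  best
}

gini_impurity <- function(n_pos, n) {
  p <- n_pos / n
  2 * p * (1 - p)
}

#' @export
predict_proba.elas_cart <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$p) stop("cart: feature count mismatch")
  p_pos <- numeric(nrow(X))
  descend <- function(node_id, rows) {
    node <- object$nodes[[node_id]]
    if (isTRUE(node$leaf)) {
      p_pos[rows] <<- node$prob
      return(invisible(NULL))
    }
    go_left <- X[rows, node$feature] <= node$threshold
    if (any(go_left)) descend(node$left, rows[go_left])
    if (any(!go_left)) descend(node$right, rows[!go_left])
  }
  if (nrow(X) > 0) descend(object$root, seq_len(nrow(X)))
  proba_matrix(p_pos)
}
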