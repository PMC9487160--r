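#' Least-confident uncertainty scores
#'
#' For each candidate the uncertainty is one minus the probability of its most
#' likely class, `1 - max_j p_ij`: 0 for a confident prediction, up to
#' `1 - 1/n_classes` for a maximally ambiguous one.
#'
#' @param probability_rows Numeric matrix, one row per candidate, columns the
#'   per-class probabilities. Rows must be non-negative and sum to 1 within
#'   `1e-6`.
#' @return Numeric vector of uncertainty scores in \[0, 1\].
#' @export
uncertainty_scores <- function(probability_rows) {
  p <- as.matrix(probability_rows)
  if (any(p < -1e-12)) stop("probability rows must be non-negative")
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    stop("probability rows must sum to 1 within 1e-6")
  }
  unname(1 - apply(p, 1L, max))
}

#' Uncertainty/diversity mixing weight
#'
#' The weight alpha multiplying the diversity term `(1 - similarity)` in the
#' batch-mode final score. Two conventions are supported:
#' \describe{
#'   \item{`"diversity_first"` (default)}{`alpha = pool / (pool + data)`:
#'     close to 1 while the unqueried pool dwarfs the training data, so early
#'     batches favor diverse samples, and decaying towards 0 as the pool
#'     drains, shifting priority to classifier uncertainty.}
#'   \item{`"literal"`}{`alpha = data / (pool + data)`, the printed form of
#'     the weighting rule, which moves in the opposite direction.}
#' }
#' The printed form contradicts the stated intent of prioritizing diversity
#' on early iterations, hence the default; see the methods vignette.
#'
#' @param n_train_data Current training-data size (>= 1).
#' @param n_train_pool Remaining pool size (>= 0).
#' @param convention `"diversity_first"` or `"literal"`.
#' @return Scalar weight in \[0, 1\].
#' @export
mixing_weight <- function(n_train_data, n_train_pool,
                          convention = c("diversity_first", "literal")) {
  convention <- match.arg(convention)
  if (n_train_data < 1) stop("n_train_data must be >= 1")
  if (n_train_pool < 0) stop("n_train_pool must be >= 0")
  total <- n_train_data + n_train_pool
  if (total == 0) stop("pool and training data cannot both be empty")
  if (convention == "diversity_first") n_train_pool / total else n_train_data / total
}

#' Similarity of candidates to an estimated set
#'
#' Each candidate's similarity is the maximum, over the estimated set (current
#' training data plus the samples already picked this round), of a bounded
#' monotone-decreasing map of Euclidean distance: `1/(1 + d)` by default or
#' `exp(-d)`. Raw distance itself is unbounded and *increases* with
#' dissimilarity, which would flip the sign of the diversity term, so the
#' bounded map is applied (see the methods vignette).
#'
#' @param candidates Numeric matrix of candidate feature rows.
#' @param estimated_set Non-empty numeric matrix with the same columns.
#' @param map `"inverse"` for `1/(1+d)` or `"exp"` for `exp(-d)`.
#' @return Numeric vector in (0, 1\], one value per candidate row.
#' @export
similarity_scores <- function(candidates, estimated_set,
                              map = c("inverse", "exp")) {
  map <- match.arg(map)
  candidates <- as_matrix_rows(candidates)
  estimated_set <- as_matrix_rows(estimated_set)
  if (nrow(estimated_set) == 0L) stop("estimated_set must be non-empty")
  if (ncol(candidates) != ncol(estimated_set)) {
    stop("candidates and estimated_set must share a column space")
  }
  d2 <- cross_dist2(candidates, estimated_set)
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
  similarity_from_distance(dmin, map)
}

similarity_from_distance <- function(d, map) {
  switch(map, inverse = 1 / (1 + d), exp = exp(-d))
}

#' Final ranked batch-mode scores
#'
#' Element-wise combination `alpha * (1 - similarity) +
#' (1 - alpha) * uncertainty`.
#'
#' @param uncertainty,similarity Equal-length score vectors.
#' @param alpha Mixing weight in \[0, 1\].
#' @return Numeric vector of final scores.
#' @export
final_scores <- function(uncertainty, similarity, alpha) {
  if (length(uncertainty) != length(similarity)) {
    stop("uncertainty and similarity must have equal length")
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * (1.0 - similarity) + (1.0 - alpha) * uncertainty
}

#' Select the next batch by ranked batch-mode sampling
#'
#' Greedy within-batch loop: the estimated set starts as the training data;
#' at each step every remaining candidate is scored by
#' `alpha * (1 - similarity) + (1 - alpha) * uncertainty`, the argmax (ties
#' broken by lowest pool index) is appended to the selection and joins the
#' estimated set, raising the similarity of its near-duplicates for later
#' steps. Uncertainty is computed once per round from the classifier's
#' class-probability output; similarity is recomputed after every selection.
#'
#' @param classifier Fitted model accepted by [predict_proba()].
#' @param pool Numeric matrix of candidate rows (the queryable pool).
#' @param train_data Numeric matrix of current training rows.
#' @param batch_size Number of samples to select (>= 1).
#' @param alpha_convention Passed to [mixing_weight()].
#' @param similarity_map Passed to [similarity_scores()].
#' @param alpha_update `"per_pick"` (default) recomputes alpha after every
#'   within-batch selection, with the picked sample moving from the pool count
#'   to the training-data count; `"frozen"` keeps the round-start alpha.
#' @param scores_log If `TRUE`, attach a per-step score table (candidate
#'   index, uncertainty, similarity, alpha, final, selected flag) as
#'   attribute `"log"` for audit export.
#' @return Integer vector of `min(batch_size, nrow(pool))` distinct pool row
#'   indices in selection order.
#' @export
rank_batch <- function(classifier, pool, train_data, batch_size,
                       alpha_convention = c("diversity_first", "literal"),
                       similarity_map = c("inverse", "exp"),
                       alpha_update = c("per_pick", "frozen"),
                       scores_log = FALSE) {
  alpha_convention <- match.arg(alpha_convention)
  similarity_map <- match.arg(similarity_map)
  alpha_update <- match.arg(alpha_update)
  pool <- as_matrix_rows(pool)
  train_data <- as_matrix_rows(train_data)
  if (nrow(pool) == 0L) stop("pool must be non-empty")
  if (batch_size < 1) stop("batch_size must be >= 1")

  prob <- predict_proba(classifier, pool)
  unc <- uncertainty_scores(prob)

  n_pool0 <- nrow(pool)
  n_data0 <- nrow(train_data)
  n_take <- min(batch_size, n_pool0)

  # running max-similarity of every pool row to the estimated set
  max_sim <- apply_max_sim(rep(0, n_pool0), pool, train_data, similarity_map)
  remaining <- rep(TRUE, n_pool0)
  selected <- integer(n_take)
  log_rows <- if (scores_log) vector("list", n_take) else NULL

  for (s in seq_len(n_take)) {
    if (alpha_update == "per_pick") {
      alpha <- mixing_weight(n_data0 + s - 1L, n_pool0 - s + 1L, alpha_convention)
    } else {
      alpha <- mixing_weight(n_data0, n_pool0, alpha_convention)
    }
    final <- final_scores(unc, max_sim, alpha)
    final[!remaining] <- -Inf
    pick <- which.max(final) # first maximum = lowest pool index tie-break
    selected[s] <- pick
    remaining[pick] <- FALSE
    if (scores_log) {
      log_rows[[s]] <- data.frame(
        step = s, candidate = seq_len(n_pool0),
        uncertainty = unc, similarity = max_sim, alpha = alpha,
        final = final, selected = seq_len(n_pool0) == pick
      )
    }
    if (s < n_take) {
      max_sim <- apply_max_sim(max_sim, pool, pool[pick, , drop = FALSE],
                               similarity_map)
    }
  }
  if (scores_log) attr(selected, "log") <- do.call(rbind, log_rows)
  selected
}

# update running per-candidate max similarity with new estimated points
apply_max_sim <- function(max_sim, candidates, new_points, map) {
  if (nrow(new_points) == 0L) return(max_sim)
  d2 <- cross_dist2(candidates, new_points)
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
  pmax(max_sim, similarity_from_distance(dmin, map))
}

# squared Euclidean cross-distance matrix via the quadratic expansion
cross_dist2 <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

as_matrix_rows <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}
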