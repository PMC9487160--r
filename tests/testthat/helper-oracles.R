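# Independent brute-force oracles. These deliberately share no code with the
# implementation paths they check: distances are accumulated per pair with
# sqrt(sum(..^2)), scores are re-derived from scratch at every greedy step,
# and AUROC is the O(n^2) pairwise comparison.

# greedy ranked-batch re-scorer: every remaining candidate is fully re-scored
# against the entire estimated set at every step
oracle_rank_batch <- function(classifier, pool, train_data, batch_size,
                              alpha_convention = "diversity_first",
                              similarity_map = "inverse",
                              alpha_update = "per_pick") {
  prob <- predict_proba(classifier, pool)
  unc <- 1 - apply(prob, 1L, max)
  smap <- function(d) if (similarity_map == "inverse") 1 / (1 + d) else exp(-d)
  n0_data <- nrow(train_data)
  n0_pool <- nrow(pool)
  est <- train_data
  remaining <- seq_len(nrow(pool))
  sel <- integer(0)
  for (s in seq_len(min(batch_size, nrow(pool)))) {
    if (alpha_update == "per_pick") {
      n_data <- n0_data + length(sel)
      n_pool <- n0_pool - length(sel)
    } else {
      n_data <- n0_data
      n_pool <- n0_pool
    }
    alpha <- if (alpha_convention == "diversity_first") {
      n_pool / (n_pool + n_data)
    } else {
      n_data / (n_pool + n_data)
    }
    best <- -Inf
    best_i <- NA_integer_
    for (i in remaining) {
      sim <- max(vapply(seq_len(nrow(est)), function(j) {
        smap(sqrt(sum((pool[i, ] - est[j, ])^2)))
      }, numeric(1)))
      sc <- alpha * (1 - sim) + (1 - alpha) * unc[i]
      if (sc > best) { # strict: ties keep the lowest candidate index
        best <- sc
        best_i <- i
      }
    }
    sel <- c(sel, best_i)
    remaining <- setdiff(remaining, best_i)
    est <- rbind(est, pool[best_i, , drop = FALSE])
  }
  sel
}

# exact pairwise-comparison AUROC, ties counting one half
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# a probability-emitting classifier with fabricated coefficients, so query
# tests control the uncertainty landscape without any fitting
mock_logreg <- function(beta, intercept = 0) {
  structure(list(family = "logreg_l2", intercept = intercept,
                 beta = as.numeric(beta), C = 1),
            class = c("elas_logreg_l2", "elas_base"))
}

# tiny hand-rolled cohort for preprocessing tests
toy_cohort <- function() {
  cohort(
    data.frame(
      sex = c("F", "M", "F", "M", "F", "M", "F", "M", "F", "M"),
      stage = c("I", "II", "III", "I", "II", "III", "I", "II", "III", "I"),
      const = rep("X", 10),
      age = c(45, 52, 61, 38, 70, 49, 55, 63, 41, 58),
      size = c(1.2, 3.4, 2.2, 0.8, 5.1, 2.9, 1.7, 4.0, 2.5, 3.1)
    ),
    schema = list(categorical = c("sex", "stage", "const"),
                  continuous = c("age", "size")),
    labels = c(0, 0, 1, 0, 1, 0, 0, 1, 0, 1)
  )
}

# deterministic separable toy matrix for learner tests
separable_xy <- function(n = 40, p = 3, gap = 3, seed = 7) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + gap * y
  list(X = X, y = y)
}
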