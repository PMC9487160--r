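#' Specification of a synthetic imbalanced cohort
#'
#' Describes a clinical-like tabular cohort with known ground truth: binary
#' outcome at a configurable prevalence, class-conditionally shifted Gaussian
#' continuous features and class-dependently tilted multinomial categorical
#' features, so the Bayes-optimal score has a closed form
#' (see [bayes_score()]) for oracle checks.
#'
#' The first `n_informative` features, in the order continuous then
#' categorical, carry signal; the rest are pure noise. `effect_size` is the
#' log-odds scale of each informative feature (Gaussian mean shift of
#' `effect_size * noise_sd`; multinomial tilt `exp(effect_size * t_l)` over
#' centered level scores `t_l`).
#'
#' @param n Cohort size.
#' @param prevalence Positive fraction, strictly between 0 and 1.
#' @param n_continuous,n_categorical Feature counts (defaults 4 and 6).
#' @param n_levels Levels per categorical feature (default 3).
#' @param n_informative Features carrying signal (default 5).
#' @param effect_size Log-odds scale of informative features (default 1).
#' @param noise_sd Continuous-feature noise SD (default 1).
#' @param exact If `TRUE` (default), force exactly `round(n * prevalence)`
#'   positives by stratified label assignment rather than Bernoulli draws.
#' @param censor_fraction Fraction of event-free patients given an early
#'   last-contact time in the generated follow-up, exercising the
#'   lost-to-follow-up exclusion (default 0.1).
#' @param horizon_rates Optional non-decreasing named vector of cumulative
#'   event fractions of the cohort at the 1/3/5-year horizons, e.g.
#'   `c("1" = 0.05, "3" = 0.2, "5" = 0.3)`; the last entry must equal
#'   `prevalence`. `NULL` spreads event times uniformly before the last
#'   horizon.
#' @param seed Integer seed.
#' @return An object of class `elas_sim_spec`.
#' @export
sim_spec <- function(n, prevalence, n_continuous = 4, n_categorical = 6,
                     n_levels = 3, n_informative = 5, effect_size = 1,
                     noise_sd = 1, exact = TRUE, censor_fraction = 0.1,
                     horizon_rates = NULL, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (n_informative > n_continuous + n_categorical) {
    stop("n_informative exceeds the total feature count")
  }
  if (exact && round(n * prevalence) < 1) {
    stop("exact mode infeasible: n * prevalence < 1")
  }
  if (!is.null(horizon_rates)) {
    horizon_rates <- sort_horizon_rates(horizon_rates, prevalence)
  }
  structure(
    list(n = as.integer(n), prevalence = prevalence,
         n_continuous = as.integer(n_continuous),
         n_categorical = as.integer(n_categorical),
         n_levels = as.integer(n_levels),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sd = noise_sd, exact = exact,
         censor_fraction = censor_fraction, horizon_rates = horizon_rates,
         seed = as.integer(seed)),
    class = "elas_sim_spec"
  )
}

sort_horizon_rates <- function(rates, prevalence) {
  if (is.null(names(rates)) || anyNA(suppressWarnings(as.numeric(names(rates))))) {
    stop("horizon_rates must be named by horizon years, e.g. c('1'=, '3'=, '5'=)")
  }
  rates <- rates[order(as.numeric(names(rates)))]
  if (any(diff(rates) < 0)) {
    stop("horizon_rates must be non-decreasing cumulative event fractions")
  }
  if (abs(rates[length(rates)] - prevalence) > 1e-9) {
    stop("the last horizon_rates entry must equal the prevalence")
  }
  rates
}

#' Generate a synthetic imbalanced cohort with known ground truth
#'
#' Labels are drawn first (exactly `round(n * prevalence)` positives in
#' exact mode), then features conditionally on class: informative continuous
#' features from `N(0, noise_sd)` vs `N(effect_size * noise_sd, noise_sd)`,
#' informative categorical features from a uniform vs an
#' `exp(effect_size * t_l)`-tilted multinomial over centered level scores.
#' The returned cohort carries the generating parameters in `$truth`, which
#' [bayes_score()] turns into the Bayes-optimal log-odds score for recovery
#' and calibration oracles.
#'
#' @param spec An [sim_spec()].
#' @return An `elas_cohort` with labels and a `$truth` record.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "elas_sim_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n
  if (spec$exact) {
    n_pos <- round(n * spec$prevalence)
    y <- integer(n)
    y[sample.int(n, n_pos)] <- 1L
  } else {
    y <- stats::rbinom(n, 1L, spec$prevalence)
  }

  cont_names <- sprintf("cont%02d", seq_len(spec$n_continuous))
  cat_names <- sprintf("cat%02d", seq_len(spec$n_categorical))
  informative <- seq_len(spec$n_informative)
  info_cont <- cont_names[informative[informative <= spec$n_continuous]]
  info_cat <- cat_names[informative[informative > spec$n_continuous] -
                          spec$n_continuous]

  truth <- list(
    prevalence = spec$prevalence,
    continuous = list(), categorical = list(),
    effect_size = spec$effect_size, noise_sd = spec$noise_sd
  )
  feats <- list()
  for (f in cont_names) {
    shift <- if (f %in% info_cont) spec$effect_size * spec$noise_sd else 0
    feats[[f]] <- stats::rnorm(n, mean = shift * y, sd = spec$noise_sd)
    truth$continuous[[f]] <- list(mu0 = 0, mu1 = shift, sd = spec$noise_sd)
  }
  levels <- paste0("L", seq_len(spec$n_levels))
  t_scores <- seq_len(spec$n_levels) - (spec$n_levels + 1) / 2
  for (f in cat_names) {
    p0 <- rep(1 / spec$n_levels, spec$n_levels)
    p1 <- if (f %in% info_cat) {
      w <- exp(spec$effect_size * t_scores) / spec$n_levels
      w / sum(w)
    } else {
      p0
    }
    draw <- function(p, m) if (m > 0) sample(levels, m, replace = TRUE, prob = p) else character()
    v <- character(n)
    v[y == 0] <- draw(p0, sum(y == 0))
    v[y == 1] <- draw(p1, sum(y == 1))
    feats[[f]] <- v
    truth$categorical[[f]] <- list(levels = levels, p0 = p0, p1 = p1)
  }

  out <- cohort(
    as.data.frame(feats, stringsAsFactors = FALSE),
    schema = list(categorical = cat_names, continuous = cont_names),
    labels = y
  )
  out$truth <- truth
  out
}

#' Bayes-optimal log-odds score under the generator's model
#'
#' The exact log posterior odds implied by the synthetic generating
#' distribution, up to the constant prior term: the sum over continuous
#' features of the Gaussian log-likelihood ratio and over categorical
#' features of `log(p1(level)/p0(level))`. Serves as the oracle score when
#' checking, e.g., that zero effect size gives chance-level AUROC and that
#' discrimination rises monotonically with effect size.
#'
#' @param x An `elas_cohort` (typically from [generate_cohort()]) or a
#'   feature `data.frame` matching the truth record.
#' @param truth A `$truth` record from [generate_cohort()].
#' @return Numeric log-odds score per row.
#' @export
bayes_score <- function(x, truth = NULL) {
  if (inherits(x, "elas_cohort")) {
    if (is.null(truth)) truth <- x$truth
    feats <- x$features
  } else {
    feats <- as.data.frame(x)
  }
  if (is.null(truth)) stop("a ground-truth record is required")
  score <- numeric(nrow(feats))
  for (f in names(truth$continuous)) {
    pr <- truth$continuous[[f]]
    v <- feats[[f]]
    score <- score + (stats::dnorm(v, pr$mu1, pr$sd, log = TRUE) -
                        stats::dnorm(v, pr$mu0, pr$sd, log = TRUE))
  }
  for (f in names(truth$categorical)) {
    pr <- truth$categorical[[f]]
    idx <- match(feats[[f]], pr$levels)
    score <- score + log(pr$p1[idx] / pr$p0[idx])
  }
  score
}

#' Generate follow-up records consistent with a cohort's labels
#'
#' Writes DFS and OS columns such that horizon labeling reproduces the
#' intended event fractions: patients labeled positive receive an event time
#' within the final (5-year) horizon — apportioned across the 1/3/5-year
#' horizons according to `spec$horizon_rates` when given, uniformly
#' otherwise — while event-free patients are followed beyond the final
#' horizon except for a `censor_fraction` share given an early last-contact
#' time, which exercises the lost-to-follow-up exclusion. The OS columns
#' mirror the DFS columns (see the methods vignette for what this generator
#' deliberately does not emulate).
#'
#' @param x An `elas_cohort` with labels.
#' @param spec The [sim_spec()] that produced it (supplies rates, censoring
#'   fraction and seed).
#' @return A follow-up `data.frame` with `dfs_time`, `dfs_event`, `os_time`,
#'   `os_event`, attachable via `x$followup <- generate_followup(x, spec)`.
#' @export
generate_followup <- function(x, spec) {
  stopifnot(inherits(x, "elas_cohort"), inherits(spec, "elas_sim_spec"))
  if (is.null(x$labels)) stop("cohort must carry labels")
  with_seed(spec$seed + 1L, generate_followup_impl(x$labels, spec))
}

generate_followup_impl <- function(y, spec) {
  n <- length(y)
  h_max <- 60 # months, the 5-year horizon
  time <- numeric(n)
  event <- as.integer(y)

  pos <- which(y == 1)
  if (length(pos) > 0) {
    if (is.null(spec$horizon_rates)) {
      time[pos] <- stats::runif(length(pos), 0, h_max)
    } else {
      bounds <- c(0, as.numeric(names(spec$horizon_rates)) * 12)
      cum_counts <- round(spec$horizon_rates * n)
      cum_counts[length(cum_counts)] <- length(pos)
      per_bin <- diff(c(0, cum_counts))
      if (any(per_bin < 0)) stop("horizon_rates imply negative bin counts")
      shuffled <- pos[sample.int(length(pos))]
      start <- 0L
      for (b in seq_along(per_bin)) {
        take <- shuffled[seq_len(per_bin[b]) + start]
        time[take] <- stats::runif(per_bin[b], bounds[b], bounds[b + 1])
        start <- start + per_bin[b]
      }
    }
  }
  neg <- which(y == 0)
  if (length(neg) > 0) {
    n_cens <- round(length(neg) * spec$censor_fraction)
    cens <- neg[sample.int(length(neg), n_cens)]
    time[neg] <- h_max + stats::runif(length(neg), 0, h_max)
    time[cens] <- stats::runif(n_cens, 0, h_max)
  }
  data.frame(dfs_time = time, dfs_event = event,
             os_time = time, os_event = event)
}

#' Cohort presets matching the six prognostic tasks
#'
#' Named presets reproducing the published task sizes and prevalences of the
#' 1/3/5-year recurrence and death labelings (7.6%/29.1%/51.9% recurrence,
#' 4.6%/21.8%/43.7% death), with a moderately informative default signal.
#'
#' @param preset One of `"1y-recurrence"`, `"1y-death"`, `"3y-recurrence"`,
#'   `"3y-death"`, `"5y-recurrence"`, `"5y-death"` (a `"table1-"` prefix is
#'   tolerated).
#' @param ... Overrides passed on to [sim_spec()] (e.g. `seed`, `n`).
#' @return An [sim_spec()].
#' @export
sim_preset <- function(preset, ...) {
  name <- sub("^table1-", "", preset)
  presets <- list(
    "1y-recurrence" = list(n = 1348, prevalence = 0.076),
    "1y-death" = list(n = 1350, prevalence = 0.046),
    "3y-recurrence" = list(n = 1016, prevalence = 0.291),
    "3y-death" = list(n = 1007, prevalence = 0.218),
    "5y-recurrence" = list(n = 727, prevalence = 0.519),
    "5y-death" = list(n = 702, prevalence = 0.437)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(sim_spec, args)
}
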