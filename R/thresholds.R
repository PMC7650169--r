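#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Fits \eqn{w_1 N(\mu_1, \sigma_1^2) + w_2 N(\mu_2, \sigma_2^2)} to a vector
#' of biomarker concentrations by expectation-maximisation. The first start
#' uses a deterministic quantile split (values below/above the median seed
#' the two components); the remaining `n_starts - 1` starts perturb the
#' split point to random quantiles. The best start by final log-likelihood
#' is returned, with components relabelled so `mean_1 <= mean_2`.
#'
#' @param values Numeric vector of concentrations (pg/ml); `NA`s dropped.
#' @param seed Integer seed controlling the random restarts.
#' @param n_starts Number of EM starts (default 10).
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @return An object of class `"mixture_fit"`: a list with `weight_1`,
#'   `weight_2`, `mean_1`, `mean_2`, `sd_1`, `sd_2`, `log_likelihood`,
#'   `converged`, `n_used`, `n_iter` and `loglik_trace` (per-iteration
#'   log-likelihoods of the winning start).
#' @details At least 20 non-missing finite values with positive sample
#'   variance are required. Component SDs are floored at `1e-6` times the
#'   overall SD to keep the likelihood bounded.
#' @export
fit_two_component_mixture <- function(values, seed = 1L, n_starts = 10L,
                                      tol = 1e-8, max_iter = 500L) {
  x <- values[is.finite(values)]
  if (length(x) < 20L)
    stop("insufficient data: need at least 20 non-missing values, got ",
         length(x))
  if (stats::var(x) <= 0) stop("degenerate data: zero sample variance")
  n <- length(x)
  sd_floor <- 1e-6 * stats::sd(x)

  em_one <- function(split_q) {
    cut <- stats::quantile(x, split_q, names = FALSE)
    lo <- x <= cut
    if (all(lo) || !any(lo)) lo <- x <= stats::median(x)
    mu <- c(mean(x[lo]), mean(x[!lo]))
    sg <- pmax(c(stats::sd(x[lo]), stats::sd(x[!lo])), sd_floor)
    sg[is.na(sg)] <- stats::sd(x)
    w <- c(mean(lo), 1 - mean(lo))
    ll_old <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      g1 <- d1 / tot
      n1 <- sum(g1); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
      sg <- c(sqrt(sum(g1 * (x - mu[1])^2) / n1),
              sqrt(sum((1 - g1) * (x - mu[2])^2) / n2))
      sg <- pmax(sg, sd_floor)
      w <- c(n1 / n, n2 / n)
    }
    list(w = w, mu = mu, sg = sg, ll = ll, converged = converged,
         n_iter = length(trace), trace = trace)
  }

  qs <- 0.5
  if (n_starts > 1L) {
    qs <- c(qs, with_local_seed(seed, stats::runif(n_starts - 1L, 0.15, 0.85)))
  }
  fits <- lapply(qs, em_one)
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]

  ord <- order(best$mu)
  structure(list(
    weight_1 = best$w[ord][1], weight_2 = best$w[ord][2],
    mean_1 = best$mu[ord][1], mean_2 = best$mu[ord][2],
    sd_1 = best$sg[ord][1], sd_2 = best$sg[ord][2],
    log_likelihood = best$ll, converged = best$converged,
    n_used = n, n_iter = best$n_iter, loglik_trace = best$trace
  ), class = "mixture_fit")
}

# evaluate RNG-consuming expression under a temporary seed, restoring state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# relabel so mean_1 <= mean_2; cut-off rules are label-invariant
order_components <- function(fit) {
  if (fit$mean_1 <= fit$mean_2) return(fit)
  fit[c("weight_1", "weight_2", "mean_1", "mean_2", "sd_1", "sd_2")] <-
    fit[c("weight_2", "weight_1", "mean_2", "mean_1", "sd_2", "sd_1")]
  fit
}

#' Component-separation diagnostic for a mixture fit
#'
#' Flags fits where the two components are effectively one population:
#' either the means are closer than `min_d` pooled SDs apart or one
#' component carries less than `min_weight` of the mass. Such fits should
#' not be used for intersection cut-offs.
#'
#' @param fit A `"mixture_fit"`.
#' @param min_d Minimum standardised mean separation (default 1).
#' @param min_weight Minimum component weight (default 0.05).
#' @return Logical: `TRUE` when the components are well separated.
#' @export
components_separated <- function(fit, min_d = 1, min_weight = 0.05) {
  pooled <- sqrt((fit$sd_1^2 + fit$sd_2^2) / 2)
  d <- (fit$mean_2 - fit$mean_1) / pooled
  d >= min_d && min(fit$weight_1, fit$weight_2) >= min_weight
}

#' Construct a dichotomisation rule
#'
#' @param analyte `"abeta42"` or `"ptau"`.
#' @param threshold Threshold in pg/ml.
#' @param positive_direction `"below"` (positivity is strictly below the
#'   threshold; amyloid convention) or `"above"` (strictly above; tau
#'   convention).
#' @param method How the threshold was derived: `"intersection"`,
#'   `"mean_sd"` or `"fixed"`.
#' @param k_sd SD multiplier (only meaningful for `"mean_sd"`).
#' @return An object of class `"cutoff_rule"`.
#' @export
cutoff_rule <- function(analyte = c("abeta42", "ptau"), threshold,
                        positive_direction = c("below", "above"),
                        method = c("fixed", "intersection", "mean_sd"),
                        k_sd = NA_real_) {
  analyte <- match.arg(analyte)
  positive_direction <- match.arg(positive_direction)
  method <- match.arg(method)
  stopifnot(is.finite(threshold))
  structure(list(analyte = analyte, threshold = threshold,
                 positive_direction = positive_direction,
                 method = method, k_sd = k_sd),
            class = "cutoff_rule")
}

#' Published cut-off rules for the CSF analytes
#'
#' The shipped defaults dichotomise CSF A\eqn{\beta}42 at < 1025 pg/ml
#' (amyloid positivity) and CSF p-Tau at > 24 pg/ml (tau positivity), so
#' classification can run without refitting a mixture. Both comparisons are
#' strict; ties at the threshold are negative.
#'
#' @param analyte `"abeta42"` or `"ptau"`.
#' @return A `"cutoff_rule"`.
#' @export
default_cutoff <- function(analyte = c("abeta42", "ptau")) {
  analyte <- match.arg(analyte)
  if (analyte == "abeta42")
    cutoff_rule("abeta42", 1025, "below", "fixed")
  else
    cutoff_rule("ptau", 24, "above", "fixed")
}

#' Density-intersection cut-off of a two-component mixture
#'
#' Returns the point between the component means where the weighted
#' component densities are equal:
#' \eqn{w_1 \phi(x; \mu_1, \sigma_1) = w_2 \phi(x; \mu_2, \sigma_2)}.
#' Solved in closed form — a quadratic in \eqn{x} when
#' \eqn{\sigma_1 \neq \sigma_2}, linear when equal — selecting the root in
#' the open interval \eqn{(\mu_1, \mu_2)}; the returned root is verified by
#' direct evaluation of both weighted densities.
#'
#' @param fit A converged `"mixture_fit"` with `mean_1 < mean_2`.
#' @param analyte Analyte tag for the resulting rule.
#' @param positive_direction Positivity direction for the resulting rule;
#'   defaults to the analyte convention (`"below"` for abeta42, `"above"`
#'   for ptau).
#' @return A `"cutoff_rule"` with `method = "intersection"`.
#' @export
intersection_cutoff <- function(fit, analyte = c("abeta42", "ptau"),
                                positive_direction = NULL) {
  analyte <- match.arg(analyte)
  if (!isTRUE(fit$converged)) stop("mixture fit did not converge")
  fit <- order_components(fit)
  if (!(fit$mean_1 < fit$mean_2))
    stop("degenerate fit: component means are not distinct")
  w1 <- fit$weight_1; w2 <- fit$weight_2
  m1 <- fit$mean_1; m2 <- fit$mean_2
  s1 <- fit$sd_1; s2 <- fit$sd_2
  # log w1 - log s1 - (x-m1)^2/(2 s1^2) = log w2 - log s2 - (x-m2)^2/(2 s2^2)
  k <- 2 * (log(w1) - log(s1) - log(w2) + log(s2))
  a <- 1 / s2^2 - 1 / s1^2
  b <- -2 * (m2 / s2^2 - m1 / s1^2)
  cc <- m2^2 / s2^2 - m1^2 / s1^2 + k
  roots <- if (abs(a) < 1e-14 * (1 / s1^2)) {
    if (abs(b) < 1e-300) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else
      (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[roots > m1 & roots < m2]
  if (length(roots) == 0L)
    stop("no density intersection between the component means; ",
         "consider mean_sd_cutoff()")
  x <- roots[1]
  d1 <- w1 * stats::dnorm(x, m1, s1)
  d2 <- w2 * stats::dnorm(x, m2, s2)
  if (abs(d1 - d2) > 1e-8 * max(d1, d2))
    stop("intersection verification failed")
  if (is.null(positive_direction))
    positive_direction <- if (analyte == "abeta42") "below" else "above"
  cutoff_rule(analyte, x, positive_direction, "intersection")
}

#' Mean-plus-SD cut-off from a mixture component
#'
#' Alternative dichotomisation rule: the threshold is the chosen component's
#' mean moved `k_sd` standard deviations toward the other component
#' (`mean + k_sd * sd` for the lower component, `mean - k_sd * sd` for the
#' upper).
#'
#' @param fit A converged `"mixture_fit"`.
#' @param component `"lower"` or `"upper"`.
#' @param k_sd SD multiplier (default 2).
#' @inheritParams intersection_cutoff
#' @return A `"cutoff_rule"` with `method = "mean_sd"`.
#' @export
mean_sd_cutoff <- function(fit, component = c("lower", "upper"), k_sd = 2,
                           analyte = c("abeta42", "ptau"),
                           positive_direction = NULL) {
  component <- match.arg(component)
  analyte <- match.arg(analyte)
  if (!isTRUE(fit$converged)) stop("mixture fit did not converge")
  fit <- order_components(fit)
  thr <- if (component == "lower") fit$mean_1 + k_sd * fit$sd_1
         else fit$mean_2 - k_sd * fit$sd_2
  if (is.null(positive_direction))
    positive_direction <- if (analyte == "abeta42") "below" else "above"
  cutoff_rule(analyte, thr, positive_direction, "mean_sd", k_sd = k_sd)
}

#' Decade-specific medial temporal atrophy threshold
#'
#' Neurodegeneration positivity uses age-banded thresholds on the Scheltens
#' medial-temporal-atrophy visual rating (0–4, half points): a participant
#' is N+ when their score is strictly greater than the returned threshold.
#' Bands: score > 1 under age 65; > 1.5 for ages 65–74; > 2 from age 75
#' (75th birthday inclusive — the oldest band; see the methods vignette for
#' the boundary convention).
#'
#' @param age Age in years (vectorised; must be positive).
#' @return Numeric threshold(s) in {1, 1.5, 2}.
#' @export
scheltens_threshold <- function(age) {
  if (any(!is.na(age) & age <= 0)) stop("age must be positive")
  ifelse(is.na(age), NA_real_,
         ifelse(age < 65, 1.0, ifelse(age < 75, 1.5, 2.0)))
}
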