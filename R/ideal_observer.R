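# Fisher-information / Cramer-Rao ideal observers for inhomogeneous-Poisson
# auditory-nerve populations. The information matrix has elements
#   I[a, b] = sum_i K_i int_0^T (1/r_i) (dr_i/da) (dr_i/db) dt,
# estimated with central finite differences and trapezoidal time integration.
# Roved stimulus parameters contribute prior information 1/nu^2 (normal
# approximation), and the variance bound on the target parameter is the
# target diagonal element of (E[I] + A)^(-1).

#' Parameter specification for an ideal-observer task
#'
#' Describes the stimulus parameter vector theta: one target parameter (the
#' discriminated quantity, e.g. f or F0) plus zero or more nuisance
#' parameters. Nuisance parameters carry a normal-approximation prior with
#' standard deviation `prior_sd` (used in the prior-information matrix) and a
#' uniform synthesis half-width `rove_half` (used when sampling the
#' expectation of the Fisher matrix).
#'
#' @param names Character names of theta's elements.
#' @param units Units per element (documentation only).
#' @param target Index of the target parameter (default 1).
#' @param prior_sd Prior SD per element; `Inf` (or `NA`) marks a fixed
#'   parameter (no prior information, no roving).
#' @param rove_half Uniform half-width per element for Monte-Carlo sampling
#'   of roved parameters (0 for fixed parameters).
#' @param step Finite-difference step per element (same units as theta).
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(names, units = rep("", length(names)), target = 1,
                       prior_sd = rep(Inf, length(names)),
                       rove_half = rep(0, length(names)),
                       step) {
  n <- length(names)
  prior_sd[is.na(prior_sd)] <- Inf
  stopifnot(length(step) == n, all(step > 0),
            target >= 1, target <= n,
            all(prior_sd > 0), all(rove_half >= 0),
            is.infinite(prior_sd[target]), rove_half[target] == 0)
  structure(list(names = names, units = units, target = target,
                 prior_sd = prior_sd, rove_half = rove_half, step = step),
            class = "param_spec")
}

#' Bind a stimulus builder and front end into a cached rate function
#'
#' @param builder Function `theta -> waveform`.
#' @param population A `population_spec`.
#' @param frontend A `frontend` (see [make_frontend()]).
#' @return A function `theta -> rate_response` that caches by theta.
#' @export
make_rate_fn <- function(builder, population, frontend) {
  cache <- new.env(parent = emptyenv())
  function(theta) {
    key <- paste(sprintf("%.17g", theta), collapse = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    resp <- frontend$simulate(builder(theta), population)
    cache[[key]] <- resp
    resp
  }
}

# trapezoidal weights for a uniform time grid
trapz_weights <- function(t) {
  n <- length(t)
  w <- c(diff(t) / 2, 0) + c(0, diff(t) / 2)
  w
}

#' Fisher information matrix of a Poisson-rate population
#'
#' Computes `I(theta)` elementwise via central finite differences at the
#' per-parameter steps, trapezoidal integration over the response window, and
#' the fibers-per-CF multiplier applied to each CF's contribution.
#'
#' @param rate_fn Function `theta -> rate_response` (see [make_rate_fn()]).
#' @param pspec A `param_spec`.
#' @param theta0 Parameter vector at which to evaluate.
#' @return An n x n symmetric positive-semidefinite matrix of class
#'   `fisher_matrix` (units 1/(unit_a x unit_b)).
#' @export
fisher_matrix <- function(rate_fn, pspec, theta0) {
  n <- length(pspec$names)
  stopifnot(length(theta0) == n)
  r0 <- rate_fn(theta0)
  if (any(r0$rates <= 0)) {
    stop("nonpositive rate encountered; Fisher integrand 1/r undefined")
  }
  w <- trapz_weights(r0$times)
  derivs <- vector("list", n)
  for (j in seq_len(n)) {
    h <- pspec$step[j]
    tp <- theta0; tp[j] <- tp[j] + h
    tm <- theta0; tm[j] <- tm[j] - h
    derivs[[j]] <- (rate_fn(tp)$rates - rate_fn(tm)$rates) / (2 * h)
  }
  inv_r <- 1 / r0$rates
  I <- matrix(0, n, n, dimnames = list(pspec$names, pspec$names))
  for (a in seq_len(n)) {
    for (b in a:n) {
      integ <- (derivs[[a]] * derivs[[b]] * inv_r) %*% w
      I[a, b] <- I[b, a] <- sum(r0$k * integ)
    }
  }
  structure(I, class = c("fisher_matrix", "matrix"))
}

#' Expected Fisher matrix over roved stimulus parameters
#'
#' Approximates `E_theta[I(theta)]` by a simple mean of `fisher_matrix` over
#' draws of the roved parameters from their uniform synthesis distributions
#' (the target parameter stays at `theta0`).
#'
#' @param rate_fn Function `theta -> rate_response`.
#' @param pspec A `param_spec`.
#' @param theta0 Nominal parameter vector.
#' @param n_draws Number of Monte-Carlo draws (default 8). With no roved
#'   parameters the single-point Fisher matrix is returned regardless.
#' @param seed Integer seed for the draws.
#' @return A `fisher_matrix`.
#' @export
expected_fisher <- function(rate_fn, pspec, theta0, n_draws = 8, seed = 1) {
  stopifnot(n_draws >= 1)
  roved <- which(pspec$rove_half > 0)
  if (length(roved) == 0) return(fisher_matrix(rate_fn, pspec, theta0))
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      th <- theta0
      th[roved] <- th[roved] +
        stats::runif(length(roved), -pspec$rove_half[roved],
                     pspec$rove_half[roved])
      th
    })
  })
  acc <- 0
  for (th in draws) acc <- acc + unclass(fisher_matrix(rate_fn, pspec, th))
  structure(acc / n_draws, class = c("fisher_matrix", "matrix"))
}

#' Prior information matrix A(theta)
#'
#' Diagonal matrix with `1/prior_sd^2` for roved parameters (the Fisher
#' information of the location of a normal prior) and 0 for fixed parameters.
#'
#' @param pspec A `param_spec`.
#' @return An n x n diagonal matrix.
#' @export
prior_info <- function(pspec) {
  a <- ifelse(is.finite(pspec$prior_sd), 1 / pspec$prior_sd^2, 0)
  diag(a, length(a), length(a))
}

#' Cramer-Rao variance bound for the target parameter
#'
#' Returns the target diagonal element of `(EI + A)^(-1)`.
#'
#' @param EI Expected Fisher matrix.
#' @param A Prior information matrix (same dimension).
#' @param target Target parameter index.
#' @return Lower bound on the variance of any unbiased estimator of the
#'   target parameter (units of target^2).
#' @export
crlb_variance <- function(EI, A = matrix(0, nrow(EI), ncol(EI)), target = 1) {
  M <- unclass(EI) + A
  inv <- tryCatch(solve(M), error = function(e) {
    stop("information matrix is singular: non-identifiable configuration")
  })
  v <- inv[target, target]
  if (!is.finite(v) || v <= 0) {
    stop("information matrix is singular: non-identifiable configuration")
  }
  v
}

#' Convert a variance bound into a threshold (JND)
#'
#' The just-noticeable difference at the 70.7% correct point is the square
#' root of the variance bound; it is also reported relative to a baseline
#' (e.g. Delta-f / f in percent).
#'
#' @param variance Variance bound (> 0), units of the target parameter
#'   squared.
#' @param baseline Baseline value of the target parameter for the relative
#'   threshold (optional).
#' @return A list with `jnd` and (if baseline given) `jnd_rel_pct`.
#' @export
threshold_from_variance <- function(variance, baseline = NULL) {
  if (!is.finite(variance) || variance <= 0) {
    stop("variance must be positive and finite")
  }
  jnd <- sqrt(variance)
  out <- list(jnd = jnd)
  if (!is.null(baseline)) out$jnd_rel_pct <- 100 * jnd / baseline
  out
}

#' Rate-place transform: replace each fiber's rate by its time average
#'
#' The rate-place observer sees only time-averaged information; downstream
#' Fisher machinery is unchanged (equivalently, per-fiber Poisson-count
#' information `T (dr_bar/dtheta)^2 / r_bar`).
#'
#' @param resp A `rate_response`.
#' @return A `rate_response` with each row constant at its time average.
#' @export
rate_place_transform <- function(resp) {
  rbar <- mean_rate_over(resp)
  resp$rates <- matrix(rbar, nrow(resp$rates), ncol(resp$rates))
  resp
}

#' Compose a rate function with the rate-place transform
#' @param rate_fn Function `theta -> rate_response`.
#' @return A rate function whose responses are time-averaged.
#' @export
rate_place_fn <- function(rate_fn) {
  function(theta) rate_place_transform(rate_fn(theta))
}

#' Monte-Carlo maximum-likelihood discrimination oracle
#'
#' Simulates two-interval forced-choice trials: one inhomogeneous-Poisson
#' spike sample drawn from `r(., theta0)` and one from `r(., theta0 + Delta)`
#' per trial, classified by comparing the exact Poisson log-likelihood ratios
#' of the two intervals against the known rate templates. For the
#' one-parameter case the proportion correct at `Delta = JND` should sit near
#' the 70.7% point achieved by a maximum-likelihood estimator.
#'
#' @param rate_fn Function `theta -> rate_response` (single-parameter task,
#'   no roved parameters).
#' @param theta0 Baseline parameter (scalar).
#' @param delta Parameter increment.
#' @param n_trials Number of 2AFC trials (>= 1).
#' @param seed Integer seed.
#' @param decim Time-grid decimation factor for the Poisson bins (default 5;
#'   bin width `decim / fs`).
#' @return Proportion of correct trials.
#' @export
oracle_ml_discrimination <- function(rate_fn, theta0, delta, n_trials,
                                     seed = 1, decim = 5L) {
  stopifnot(n_trials >= 1, length(theta0) == 1)
  r0 <- rate_fn(theta0)
  r1 <- rate_fn(theta0 + delta)
  idx <- seq(1, ncol(r0$rates), by = decim)
  dt <- (r0$times[2] - r0$times[1]) * decim
  lam0 <- as.vector(r0$rates[, idx] * r0$k) * dt  # CF-major flatten
  lam1 <- as.vector(r1$rates[, idx] * r1$k) * dt
  w <- log(lam1 / lam0)
  correct <- 0L
  with_seed(seed, {
    chunk <- max(1L, min(n_trials, floor(2e6 / length(lam0))))
    done <- 0L
    while (done < n_trials) {
      m <- min(chunk, n_trials - done)
      # interval A from theta0 + delta, interval B from theta0
      nA <- matrix(stats::rpois(m * length(lam1), rep(lam1, each = m)), m)
      nB <- matrix(stats::rpois(m * length(lam0), rep(lam0, each = m)), m)
      s <- as.vector(nA %*% w) - as.vector(nB %*% w)
      correct <- correct + sum(s > 0) + sum(s == 0) / 2
      done <- done + m
    }
  })
  correct / n_trials
}
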