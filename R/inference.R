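#' Prior specification for the kinetic parameters
#'
#' Independent uniform priors on the (by default) log10-transformed
#' parameters (k_a, k_d, c_sat) — wide, uninformative scale priors for
#' rate constants spanning decades.
#'
#' @param lower,upper Named numeric vectors with elements \code{k_a},
#'   \code{k_d}, \code{c_sat}: prior bounds on the natural scale.
#' @param log_scale Logical; sample in log-space (log-uniform prior).
#' @return An object of class \code{prior_spec}.
#' @examples
#' prior_spec()  # the wide defaults
#' @export
prior_spec <- function(lower = c(k_a = 1e-4, k_d = 1e-7, c_sat = 1e-5),
                       upper = c(k_a = 1e2, k_d = 1e-1, c_sat = 1),
                       log_scale = TRUE) {
  nm <- c("k_a", "k_d", "c_sat")
  stopifnot(all(nm %in% names(lower)), all(nm %in% names(upper)))
  lower <- lower[nm]; upper <- upper[nm]
  if (any(!(lower < upper))) stop("prior lower bounds must be below upper bounds")
  if (log_scale && any(lower <= 0)) stop("log-scale prior needs positive bounds")
  structure(list(lower = lower, upper = upper, log_scale = isTRUE(log_scale),
                 names = nm), class = "prior_spec")
}

# log prior density (up to a constant) at theta in sampling space
.log_prior <- function(theta, prior) {
  b_lo <- if (prior$log_scale) log(prior$lower) else prior$lower
  b_hi <- if (prior$log_scale) log(prior$upper) else prior$upper
  if (any(theta < b_lo) || any(theta > b_hi)) -Inf else 0
}

.to_natural <- function(theta, prior) {
  p <- if (prior$log_scale) exp(theta) else theta
  names(p) <- prior$names
  p
}

#' Gaussian log-likelihood of a kinetic trace
#'
#' Residuals between the measured normalized trace and the model
#' \code{\link{integrated_fraction}} evaluated on the trace's time grid,
#' with independent Gaussian noise.  Non-physical parameters or an
#' integrator failure give \code{-Inf} (failure message attached as the
#' \code{"diagnostic"} attribute).
#'
#' @param trace A \code{\link{kinetic_trace}}.
#' @param params A \code{\link{kinetic_params}}.
#' @param geometry A \code{\link{vesicle_geometry}}.
#' @param c_total Total polymer concentration (mass fraction).
#' @param sigma Noise standard deviation; scalar, vector, or \code{NULL} to
#'   use \code{trace$sigma}.
#' @return Log-density (single number).
#' @export
log_likelihood <- function(trace, params, geometry, c_total, sigma = NULL) {
  if (is.null(sigma)) sigma <- trace$sigma
  if (is.null(sigma)) stop("no noise scale: supply 'sigma' or a trace with per-point errors")
  sigma <- rep_len(sigma, length(trace$times))
  if (any(!(sigma > 0))) return(-Inf)
  if (params$k_a < 0 || params$k_d < 0 || (params$k_a > 0 && !(params$c_sat > 0)))
    return(-Inf)
  f <- tryCatch(
    integrated_fraction(simulate_kinetics(params, geometry, c_total,
                                          times = trace$times,
                                          rtol = 1e-8, atol = 1e-12)),
    error = function(e) e)
  if (inherits(f, "error"))
    return(structure(-Inf, diagnostic = conditionMessage(f)))
  r <- trace$intensity - f
  -0.5 * sum(log(2 * pi * sigma^2) + (r / sigma)^2)
}

# log posterior in sampling space; returns -Inf outside support
.log_post <- function(theta, trace, prior, geometry, c_total, sigma) {
  lp <- .log_prior(theta, prior)
  if (!is.finite(lp)) return(-Inf)
  p <- .to_natural(theta, prior)
  ll <- log_likelihood(trace, kinetic_params(p[["k_a"]], p[["k_d"]], p[["c_sat"]]),
                       geometry, c_total, sigma)
  lp + ll
}

#' Fit the kinetic model by affine-invariant ensemble MCMC
#'
#' Samples the posterior of (k_a, k_d, c_sat) given a normalized kinetic
#' trace, using the Goodman-Weare stretch move over an ensemble of walkers
#' (the affine-invariant scheme popularized by the emcee sampler), with a
#' log-uniform prior by default.  Walkers are initialized in a small ball
#' around the best of a seeded log-uniform prior scatter, optionally
#' polished by a short Nelder-Mead ascent.  Fully reproducible given
#' \code{seed}.
#'
#' @param trace A \code{\link{kinetic_trace}}.
#' @param prior A \code{\link{prior_spec}}.
#' @param geometry A \code{\link{vesicle_geometry}}.
#' @param c_total Total polymer concentration (mass fraction).
#' @param n_walkers Number of walkers (>= 2 * number of parameters).
#' @param n_steps Number of ensemble steps recorded.
#' @param seed Integer RNG seed.
#' @param sigma Noise scale override (else the trace's per-point errors).
#' @param a Stretch-move scale parameter (default 2).
#' @param n_scout Size of the prior scatter used for initialization.
#' @param polish Logical; run a short Nelder-Mead ascent from the best
#'   scout point before placing the walker ball.
#' @return An object of class \code{posterior}: list with \code{samples}
#'   (array steps x walkers x 3, natural scale), \code{log_prob}
#'   (steps x walkers), \code{param_names}, \code{acceptance} (fraction),
#'   \code{seed}, \code{prior}.
#' @export
fit_mcmc <- function(trace, prior = prior_spec(), geometry, c_total,
                     n_walkers = 32, n_steps = 1000, seed = 1,
                     sigma = NULL, a = 2, n_scout = 64, polish = TRUE) {
  d <- 3L
  force(seed)   # evaluate before the RNG state is captured
  if (n_walkers < 2 * d) stop("need n_walkers >= 2 * n_params (= 6)")
  if (!is.null(trace$sigma) && is.null(sigma)) sigma <- NULL  # use trace errors
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  b_lo <- if (prior$log_scale) log(prior$lower) else prior$lower
  b_hi <- if (prior$log_scale) log(prior$upper) else prior$upper
  lpost <- function(theta) .log_post(theta, trace, prior, geometry, c_total, sigma)

  # initialization: seeded prior scatter, optional short polish, small ball
  scout <- matrix(stats::runif(n_scout * d, rep(b_lo, each = n_scout),
                               rep(b_hi, each = n_scout)), ncol = d)
  scout_lp <- apply(scout, 1, lpost)
  if (all(!is.finite(scout_lp)))
    stop("no finite-posterior starting point found inside the prior")
  x0 <- scout[which.max(scout_lp), ]
  if (polish) {
    opt <- stats::optim(x0, function(th) -lpost(th), method = "Nelder-Mead",
                        control = list(maxit = 200))
    if (is.finite(opt$value)) x0 <- opt$par
  }
  walkers <- matrix(rep(x0, each = n_walkers), ncol = d) +
    matrix(stats::rnorm(n_walkers * d, sd = 0.02), ncol = d)
  walkers <- pmin(pmax(walkers, rep(b_lo, each = n_walkers) + 1e-9),
                  rep(b_hi, each = n_walkers) - 1e-9)
  lp <- apply(walkers, 1, lpost)

  chain <- array(NA_real_, dim = c(n_steps, n_walkers, d))
  lp_chain <- matrix(NA_real_, n_steps, n_walkers)
  n_acc <- 0L
  for (s in seq_len(n_steps)) {
    for (k in seq_len(n_walkers)) {
      j <- sample.int(n_walkers - 1L, 1L)
      if (j >= k) j <- j + 1L
      z <- ((a - 1) * stats::runif(1) + 1)^2 / a
      prop <- walkers[j, ] + z * (walkers[k, ] - walkers[j, ])
      lp_prop <- lpost(prop)
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < (d - 1) * log(z) + lp_prop - lp[k]) {
        walkers[k, ] <- prop
        lp[k] <- lp_prop
        n_acc <- n_acc + 1L
      }
    }
    chain[s, , ] <- walkers
    lp_chain[s, ] <- lp
  }
  acc <- n_acc / (n_steps * n_walkers)
  if (acc < 0.01)
    warning(sprintf("ensemble nearly stuck: acceptance fraction %.3f < 0.01", acc))
  nat <- if (prior$log_scale) exp(chain) else chain
  structure(list(samples = nat, log_prob = lp_chain,
                 param_names = prior$names, acceptance = acc,
                 seed = seed, prior = prior, n_walkers = n_walkers,
                 n_steps = n_steps),
            class = "posterior")
}

#' @export
print.posterior <- function(x, ...) {
  cat(sprintf("<posterior> %d steps x %d walkers over (%s); acceptance %.2f, seed %d\n",
              x$n_steps, x$n_walkers, paste(x$param_names, collapse = ", "),
              x$acceptance, x$seed))
  invisible(x)
}

#' Flatten a posterior into a samples matrix
#'
#' @param post A \code{posterior}.
#' @param burn_in Fraction (in [0,1)) or integer number of initial steps
#'   discarded; default 0.2.
#' @param thin Keep every \code{thin}-th step.
#' @return Matrix (samples x parameters) on the natural scale.
#' @export
posterior_samples <- function(post, burn_in = 0.2, thin = 1L) {
  nb <- if (burn_in < 1) floor(burn_in * post$n_steps) else as.integer(burn_in)
  if (nb >= post$n_steps) stop("burn-in leaves no samples")
  keep <- seq.int(nb + 1L, post$n_steps, by = thin)
  m <- apply(post$samples[keep, , , drop = FALSE], 3, c)
  colnames(m) <- post$param_names
  m
}

# split-chain R-hat: each walker split in half, rank-free classic formula
.split_rhat <- function(chain_sw) {   # steps x walkers
  n <- floor(nrow(chain_sw) / 2)
  if (n < 2) return(NA_real_)
  halves <- cbind(chain_sw[seq_len(n), , drop = FALSE],
                  chain_sw[seq.int(nrow(chain_sw) - n + 1, nrow(chain_sw)), ,
                           drop = FALSE])
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (!(W > 0)) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summary
#'
#' Per-parameter median, 16/84 and 2.5/97.5 percentiles, the MAP sample,
#' split-chain R-hat convergence diagnostics and the acceptance fraction.
#'
#' @inheritParams posterior_samples
#' @return An object of class \code{posterior_summary}: list with
#'   \code{table} (data frame of quantiles per parameter), \code{map}
#'   (named vector), \code{rhat} (named vector), \code{acceptance},
#'   \code{n_samples}.
#' @export
posterior_summary <- function(post, burn_in = 0.2, thin = 1L) {
  m <- posterior_samples(post, burn_in, thin)
  qs <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.16, 0.5, 0.84, 0.975)))
  tab <- data.frame(parameter = post$param_names,
                    median = qs[, 3], q16 = qs[, 2], q84 = qs[, 4],
                    q025 = qs[, 1], q975 = qs[, 5], row.names = NULL)
  imap <- which(post$log_prob == max(post$log_prob), arr.ind = TRUE)[1, ]
  map <- post$samples[imap[1], imap[2], ]
  names(map) <- post$param_names
  nb <- if (burn_in < 1) floor(burn_in * post$n_steps) else as.integer(burn_in)
  keep <- seq.int(nb + 1L, post$n_steps)
  rhat <- vapply(seq_along(post$param_names), function(p)
    .split_rhat(log(post$samples[keep, , p])), numeric(1))
  names(rhat) <- post$param_names
  structure(list(table = tab, map = map, rhat = rhat,
                 acceptance = post$acceptance, n_samples = nrow(m)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  cat(sprintf("  R-hat: %s; acceptance %.2f; %d samples\n",
              paste(sprintf("%s %.3f", names(x$rhat), x$rhat), collapse = ", "),
              x$acceptance, x$n_samples))
  invisible(x)
}

#' Inverse-variance weighted average
#'
#' @param values Numeric vector of estimates.
#' @param errors Positive standard errors, same length.
#' @return An object of class \code{weighted_estimate}: list with
#'   \code{value}, \code{uncertainty} = (sum of weights)^(-1/2), and
#'   \code{n_inputs}.
#' @export
weighted_average <- function(values, errors) {
  stopifnot(length(values) == length(errors), length(values) >= 1)
  if (any(!(errors > 0))) stop("all errors must be strictly positive")
  w <- 1 / errors^2
  structure(list(value = sum(w * values) / sum(w),
                 uncertainty = 1 / sqrt(sum(w)),
                 n_inputs = length(values)),
            class = "weighted_estimate")
}

#' @export
print.weighted_estimate <- function(x, ...) {
  cat(sprintf("<weighted_estimate> %g +/- %g (n = %d)\n",
              x$value, x$uncertainty, x$n_inputs))
  invisible(x)
}

#' Extrapolate a parameter in molecular weight
#'
#' \code{mode = "exponential"}: weighted least-squares fit of
#' \code{ln(value)} against MW (i.e. \code{value = A exp(B mw)}), evaluated
#' at \code{target_mw}, with the uncertainty propagated from the fit
#' covariance.  \code{mode = "constant"}: MW-independent value, the
#' inverse-variance \code{\link{weighted_average}}.
#'
#' @param mw Molecular weights (kg/mol).
#' @param values Parameter values at those MWs (positive for exponential).
#' @param errors Standard errors (optional for exponential with > 2 points).
#' @param target_mw MW at which to predict.
#' @param mode \code{"exponential"} or \code{"constant"}.
#' @return List with \code{value}, \code{uncertainty}, \code{mode},
#'   \code{target_mw} and (exponential mode) \code{coef} = c(lnA, B).
#' @export
mw_extrapolate <- function(mw, values, errors = NULL, target_mw,
                           mode = c("exponential", "constant")) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (is.null(errors)) errors <- rep(1, length(values))
    est <- weighted_average(values, errors)
    return(list(value = est$value, uncertainty = est$uncertainty,
                mode = mode, target_mw = target_mw))
  }
  stopifnot(length(mw) == length(values), length(mw) >= 2)
  if (any(!(values > 0)))
    stop("exponential mode requires strictly positive values")
  y <- log(values)
  # errors on value -> errors on ln(value) by delta method
  w <- if (!is.null(errors)) {
    if (any(!(errors > 0))) stop("all errors must be strictly positive")
    (values / errors)^2
  } else rep(1, length(values))
  X <- cbind(1, mw)
  XtWX <- crossprod(X, w * X)
  beta <- solve(XtWX, crossprod(X, w * y))
  xt <- c(1, target_mw)
  pred_ln <- drop(xt %*% beta)
  if (!is.null(errors)) {
    # propagate measurement errors through the weighted normal equations
    var_ln <- drop(xt %*% solve(XtWX) %*% xt)
  } else {
    res <- y - drop(X %*% beta)
    dfree <- length(y) - 2L
    s2 <- if (dfree > 0) sum(res^2) / dfree else 0
    var_ln <- s2 * drop(xt %*% solve(XtWX) %*% xt)
  }
  val <- exp(pred_ln)
  list(value = val, uncertainty = val * sqrt(max(var_ln, 0)),
       mode = mode, target_mw = target_mw,
       coef = c(lnA = beta[1], B = beta[2]))
}

#' Predicted inner-volume filling curve with uncertainty band
#'
#' Simulates the filling ratio \code{c_i(t)/c_o(t)} at the (typically
#' MW-extrapolated) point estimates and propagates parameter uncertainties
#' by seeded parameter-space Monte Carlo: each draw takes the parameters
#' log-normally around the point estimates (coefficient of variation
#' \code{err/value}); the band is the pointwise 2.5/97.5 percentile range.
#'
#' @param params A \code{\link{kinetic_params}} at the point estimates.
#' @param errors Named numeric vector of 1-sigma absolute uncertainties for
#'   \code{k_a}, \code{k_d}, \code{c_sat} (0 allowed).
#' @param geometry A \code{\link{vesicle_geometry}}.
#' @param c_total Total polymer concentration.
#' @param times Time grid (s).
#' @param n_draws Monte Carlo draws (default 200).
#' @param seed RNG seed.
#' @return List with \code{times}, \code{central}, \code{lower},
#'   \code{upper} (filling-ratio curves) and \code{n_skipped} draws.
#' @export
predict_filling <- function(params, errors, geometry, c_total, times,
                            n_draws = 200, seed = 1) {
  force(seed)   # evaluate before the RNG state is captured
  stopifnot(all(c("k_a", "k_d", "c_sat") %in% names(errors)),
            all(errors >= 0))
  fill <- function(p) {
    tr <- simulate_kinetics(p, geometry, c_total, times)
    ifelse(tr$c_o > 0, tr$c_i / tr$c_o, NA_real_)
  }
  central <- fill(params)
  if (all(errors == 0))
    return(list(times = times, central = central, lower = central,
                upper = central, n_skipped = 0L))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  p0 <- c(k_a = params$k_a, k_d = params$k_d, c_sat = params$c_sat)
  cv <- errors[names(p0)] / p0
  draws <- matrix(NA_real_, n_draws, length(times))
  n_skip <- 0L
  for (i in seq_len(n_draws)) {
    p <- p0 * exp(stats::rnorm(3, mean = 0, sd = cv))
    ok <- tryCatch({
      draws[i, ] <- fill(kinetic_params(p[["k_a"]], p[["k_d"]], p[["c_sat"]]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) n_skip <- n_skip + 1L
  }
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  list(times = times, central = central, lower = qs[1, ], upper = qs[2, ],
       n_skipped = n_skip)
}
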