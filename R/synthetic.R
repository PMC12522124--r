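#' Simulation scenario
#'
#' Bundles geometry, kinetic parameters, polymer descriptor, total
#' concentration and noise level, with a seed so every generated data set
#' is reproducible.
#'
#' @param name Label.
#' @param geometry A \code{\link{vesicle_geometry}}.
#' @param params A \code{\link{kinetic_params}}.
#' @param polymer A \code{\link{polymer_spec}}.
#' @param c_total Total polymer concentration (mass fraction).
#' @param sigma Noise standard deviation of the normalized kinetic trace.
#' @param seed Integer seed.
#' @return An object of class \code{scenario}.
#' @export
scenario <- function(name, geometry, params, polymer, c_total = 0.01,
                     sigma = 0.02, seed = 1L) {
  stopifnot(inherits(geometry, "vesicle_geometry"),
            inherits(params, "kinetic_params"),
            inherits(polymer, "polymer_spec"), c_total > 0, sigma >= 0)
  structure(list(name = name, geometry = geometry, params = params,
                 polymer = polymer, c_total = c_total, sigma = sigma,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s (%s): k_a = %g, k_d = %g, c_sat = %g, c_total = %g, sigma = %g, seed = %d\n",
              x$name, x$polymer$name, x$params$k_a, x$params$k_d,
              x$params$c_sat, x$c_total, x$sigma, x$seed))
  invisible(x)
}

#' Shipped scenario presets
#'
#' Three regimes mirroring the qualitatively different translocation
#' mechanisms: a nearly homogeneous-polarity AAP (moderate adsorption,
#' moderate membrane capacity, fast desorption), a strongly amphiphilic AAP
#' (high membrane capacity, slow desorption) and a triblock copolymer (very
#' fast adsorption, highest capacity, slowest desorption).  The numeric
#' values are illustrative regime markers, not fitted constants.
#'
#' @param name One of \code{"homogeneous"}, \code{"amphiphilic"},
#'   \code{"triblock"}.
#' @param seed Seed stored in the scenario.
#' @return A \code{\link{scenario}}.
#' @export
scenario_preset <- function(name = c("homogeneous", "amphiphilic", "triblock"),
                            seed = 1L) {
  name <- match.arg(name)
  geom <- vesicle_geometry(R = 44, d = 4, c_lipid = 20)
  sc <- switch(name,
    homogeneous = list(params = kinetic_params(5e-2, 5e-4, 0.02),
                       poly = polymer_spec("P(C4EG4)-like", 4, 4, mw = 2, lcst = 26)),
    amphiphilic = list(params = kinetic_params(1e-1, 5e-5, 0.08),
                       poly = polymer_spec("P(C14EG47)-like", 14, 47, mw = 16)),
    triblock = list(params = kinetic_params(5e-1, 2e-5, 0.1),
                    poly = polymer_spec("triblock-like", mw = 13, triblock = TRUE)))
  scenario(name, geom, sc$params, sc$poly, c_total = 0.01, sigma = 0.02,
           seed = seed)
}

# log-spaced kinetic time grid resolving the adsorption and desorption regimes
.kinetic_time_grid <- function(params, n_points, t_span = 5) {
  t0 <- 0.05 / max(params$k_a, 1e-12)
  t1 <- t_span / max(params$k_d, 1e-12)
  exp(seq(log(t0), log(t1), length.out = n_points))
}

#' Generate a noisy kinetic trace
#'
#' Simulates the scenario, forms the normalized LUV-integrated fraction on
#' a log-spaced time grid covering both the adsorption and the desorption
#' regime, and adds i.i.d. Gaussian noise.  The generating seed is logged in
#' the trace's \code{sigma}/metadata and the global RNG state is restored.
#'
#' @param scn A \code{\link{scenario}}.
#' @param n_points Number of time points (>= 10).
#' @param sigma Noise sd; defaults to the scenario's.
#' @param seed Seed; defaults to the scenario's.
#' @param t_span Grid end as a multiple of 1/k_d.
#' @return A \code{\link{kinetic_trace}} with attribute \code{"truth"}
#'   (the generating scenario).
#' @export
gen_kinetic_trace <- function(scn, n_points = 100, sigma = scn$sigma,
                              seed = scn$seed, t_span = 5) {
  stopifnot(n_points >= 10)
  force(seed); force(sigma)   # evaluate before the RNG state is captured
  times <- .kinetic_time_grid(scn$params, n_points, t_span)
  traj <- simulate_kinetics(scn$params, scn$geometry, scn$c_total, times)
  f <- integrated_fraction(traj)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  y <- f + if (sigma > 0) stats::rnorm(n_points, sd = sigma) else 0
  tr <- kinetic_trace(times, y, sigma = max(sigma, 1e-6))
  attr(tr, "truth") <- scn
  tr
}

#' Generate a (multi-)exponential echo decay
#'
#' @param D Diffusion coefficients (m^2/s) of the species.
#' @param fractions Signal fractions summing to 1.
#' @param seq A \code{\link{pulse_sequence}}.
#' @param g_max Maximum gradient (T/m); the decay is sampled on a linear
#'   g grid from 0 to \code{g_max}.
#' @param n_points Number of gradient points.
#' @param noise Additive Gaussian noise sd on the normalized intensity.
#' @param seed RNG seed.
#' @return An \code{\link{echo_decay}}.
#' @export
gen_echo_decay <- function(D, fractions, seq, g_max = 1, n_points = 16,
                           noise = 0, seed = 1L) {
  stopifnot(length(D) == length(fractions))
  force(seed); force(noise)   # evaluate before the RNG state is captured
  if (abs(sum(fractions) - 1) > 1e-9) stop("'fractions' must sum to 1")
  g <- seq(0, g_max, length.out = n_points)
  q2 <- wavenumber(seq, g)^2
  I <- sapply(g, function(gg)
    sum(fractions * echo_attenuation(D, seq, g = gg)))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  if (noise > 0) I <- I + stats::rnorm(n_points, sd = noise)
  echo_decay(q2, I, errors = if (noise > 0) rep(noise, n_points) else NULL)
}

#' Generate noisy reflectivity curves for a set of contrasts
#'
#' Forward reflectivity of the stack under each contrast, multiplied by
#' (1 + Gaussian relative noise); the \code{dR} column carries the noise
#' level.
#'
#' @param stack A \code{\link{slab_stack}}.
#' @param contrasts List of solvent \code{\link{nr_material}}s.
#' @param q q_z grid (1/A).
#' @param rel_noise Relative Gaussian noise level.
#' @param seed RNG seed.
#' @param dq_q Resolution FWHM passed to \code{\link{reflectivity}}.
#' @return List of \code{\link{reflectivity_curve}}s, one per contrast.
#' @export
gen_reflectivity <- function(stack, contrasts, q, rel_noise = 0, seed = 1L,
                             dq_q = 0) {
  force(seed); force(rel_noise)   # evaluate before the RNG state is captured
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  lapply(contrasts, function(ct) {
    rc <- reflectivity(stack, ct, q, dq_q = dq_q)
    R <- rc$R
    if (rel_noise > 0) R <- R * (1 + stats::rnorm(length(q), sd = rel_noise))
    reflectivity_curve(q, pmax(R, .Machine$double.xmin),
                       dR = pmax(rel_noise * rc$R, 1e-15),
                       contrast = ct$name)
  })
}
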