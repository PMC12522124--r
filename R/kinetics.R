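#' Kinetic rate parameters
#'
#' The three parameters of the saturating adsorption/desorption exchange
#' model: the adsorption rate constant \code{k_a} (1/s, acting on the
#' reservoir concentration at both membrane faces), the total desorption rate
#' constant \code{k_d} (1/s, split equally between the two faces) and the
#' saturation polymer concentration of the membrane \code{c_sat} (mass
#' fraction; adsorption is blocked by the factor \code{1 - c_m/c_sat}).
#'
#' @param k_a Adsorption rate constant (1/s), >= 0.
#' @param k_d Total desorption rate constant (1/s), >= 0.
#' @param c_sat Membrane saturation concentration (mass fraction); must be
#'   positive whenever \code{k_a > 0}. \code{Inf} gives linear partitioning.
#' @return An object of class \code{kinetic_params}.
#' @examples
#' kinetic_params(k_a = 0.05, k_d = 5e-4, c_sat = 0.02)
#' @export
kinetic_params <- function(k_a, k_d, c_sat) {
  stopifnot(is.numeric(k_a), is.numeric(k_d), is.numeric(c_sat))
  if (k_a < 0 || k_d < 0) stop("rate constants must be non-negative")
  if (k_a > 0 && !(c_sat > 0))
    stop("'c_sat' must be positive when k_a > 0 (saturation factor undefined)")
  structure(list(k_a = as.numeric(k_a), k_d = as.numeric(k_d),
                 c_sat = as.numeric(c_sat)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> k_a = %g /s, k_d = %g /s, c_sat = %g\n",
              x$k_a, x$k_d, x$c_sat))
  invisible(x)
}

#' Compartment state
#'
#' @param c_o,c_m,c_i Non-negative polymer concentrations in the outer
#'   solution, membrane and inner vesicle volume (common units).
#' @return An object of class \code{compartment_state}.
#' @export
compartment_state <- function(c_o, c_m, c_i) {
  v <- c(c_o = c_o, c_m = c_m, c_i = c_i)
  if (any(!is.finite(v)) || any(v < 0))
    stop("compartment concentrations must be finite and non-negative")
  structure(as.list(v), class = "compartment_state")
}

#' Time derivatives of the compartment concentrations
#'
#' The minimal symmetric rate-equation form: adsorption from both aqueous
#' reservoirs with the same \code{k_a}, blocked by the membrane saturation
#' factor \code{S = 1 - c_m/c_sat}; total desorption \code{k_d} from the
#' membrane split equally between the two faces.  Fluxes are per membrane
#' volume, so the aqueous compartments carry \code{phi_mem/phi} prefactors
#' and the phi-weighted total concentration is conserved identically.
#'
#' \deqn{dc_m/dt = k_a (c_o + c_i) S - k_d c_m}
#' \deqn{dc_i/dt = (\phi_{mem}/\phi_{in}) [ (k_d/2) c_m - k_a c_i S ]}
#' \deqn{dc_o/dt = (\phi_{mem}/\phi_{out}) [ (k_d/2) c_m - k_a c_o S ]}
#'
#' @param state A \code{\link{compartment_state}} (or named list with
#'   \code{c_o}, \code{c_m}, \code{c_i}).
#' @param params A \code{\link{kinetic_params}}.
#' @param geometry A \code{\link{vesicle_geometry}}.
#' @return Named numeric vector \code{c(dc_o, dc_m, dc_i)} in 1/s units of
#'   the concentration scale.
#' @export
rate_equations <- function(state, params, geometry) {
  if (params$k_a > 0 && !(params$c_sat > 0))
    stop("c_sat = 0 with k_a > 0 is not admissible")
  S <- if (is.finite(params$c_sat) && params$c_sat > 0)
    1 - state$c_m / params$c_sat else 1
  dm <- params$k_a * (state$c_o + state$c_i) * S - params$k_d * state$c_m
  do <- if (geometry$phi_out > 0)
    (geometry$phi_mem / geometry$phi_out) *
      (params$k_d / 2 * state$c_m - params$k_a * state$c_o * S) else 0
  di <- if (geometry$phi_in > 0)
    (geometry$phi_mem / geometry$phi_in) *
      (params$k_d / 2 * state$c_m - params$k_a * state$c_i * S) else 0
  c(dc_o = do, dc_m = dm, dc_i = di)
}

#' Simulate the translocation kinetics
#'
#' Integrates the three-compartment rate equations with a stiff-safe solver
#' (\code{deSolve::lsoda} driving the compiled right-hand side).  By default
#' all polymer starts in the outer solution: \code{c_o(0) = c_total/phi_out},
#' \code{c_m(0) = c_i(0) = 0}.
#'
#' @param params A \code{\link{kinetic_params}}.
#' @param geometry A \code{\link{vesicle_geometry}}.
#' @param c_total Total polymer concentration of the sample (mass fraction,
#'   phi-weighted over compartments).
#' @param times Strictly increasing time grid in seconds.  A leading 0 is
#'   prepended internally if absent (integration starts at the initial state)
#'   but only the requested times are returned.
#' @param state0 Optional \code{\link{compartment_state}} overriding the
#'   all-outside initial condition; its phi-weighted total then defines
#'   \code{c_total}.
#' @param engine \code{"compiled"} (default) for the C right-hand side,
#'   \code{"R"} for the pure-R \code{\link{rate_equations}} (cross-check path).
#' @param rtol,atol Integrator tolerances.
#' @return An object of class \code{trajectory}: a data frame with columns
#'   \code{time}, \code{c_o}, \code{c_m}, \code{c_i} and attributes
#'   \code{geometry}, \code{params}, \code{c_total}.
#' @examples
#' geom <- vesicle_geometry(44, 4, 20)
#' par  <- kinetic_params(0.05, 5e-4, 0.02)
#' traj <- simulate_kinetics(par, geom, c_total = 0.01,
#'                           times = 10^seq(0, 4, length.out = 50))
#' @export
simulate_kinetics <- function(params, geometry, c_total, times,
                              state0 = NULL, engine = c("compiled", "R"),
                              rtol = 1e-9, atol = 1e-12) {
  engine <- match.arg(engine)
  stopifnot(is.numeric(times), length(times) >= 1)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (any(times < 0)) stop("'times' must be non-negative")
  if (is.null(state0)) {
    stopifnot(is.numeric(c_total), c_total >= 0)
    y0 <- c(c_o = c_total / geometry$phi_out, c_m = 0, c_i = 0)
  } else {
    y0 <- c(c_o = state0$c_o, c_m = state0$c_m, c_i = state0$c_i)
    c_total <- geometry$phi_out * y0[["c_o"]] + geometry$phi_mem * y0[["c_m"]] +
      geometry$phi_in * y0[["c_i"]]
  }
  tgrid <- if (times[1] > 0) c(0, times) else times
  pvec <- c(params$k_a, params$k_d, params$c_sat,
            geometry$phi_out, geometry$phi_mem, geometry$phi_in)
  sol <- if (engine == "compiled") {
    deSolve::lsoda(y = y0, times = tgrid, func = "luvtrans_derivs",
                   parms = pvec, dllname = "luvtrans",
                   initfunc = "luvtrans_init", rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, y, p) {
      st <- list(c_o = y[[1]], c_m = y[[2]], c_i = y[[3]])
      list(unname(rate_equations(st, params, geometry)))
    }
    deSolve::lsoda(y = y0, times = tgrid, func = rhs, parms = NULL,
                   rtol = rtol, atol = atol)
  }
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop(sprintf("ODE integration failed (lsoda istate = %d); parameters k_a=%g k_d=%g c_sat=%g",
                 diagn[1], params$k_a, params$k_d, params$c_sat))
  sol <- as.data.frame(sol)
  names(sol) <- c("time", "c_o", "c_m", "c_i")
  if (times[1] > 0) sol <- sol[-1, , drop = FALSE]
  rownames(sol) <- NULL
  # clip solver-scale negative undershoot
  sol$c_m <- pmax(sol$c_m, 0)
  sol$c_i <- pmax(sol$c_i, 0)
  structure(sol, geometry = geometry, params = params, c_total = c_total,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  g <- attr(x, "geometry"); p <- attr(x, "params")
  cat(sprintf("<trajectory> %d time points, t in [%g, %g] s\n",
              nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  k_a = %g /s, k_d = %g /s, c_sat = %g, c_total = %g\n",
              p$k_a, p$k_d, p$c_sat, attr(x, "c_total")))
  invisible(x)
}

#' Equilibrium compartment state
#'
#' Closed form from detailed balance.  At equilibrium the inner and outer
#' aqueous concentrations are equal (\code{c_i = c_o = c_eq}; passive,
#' non-directional transport) and the membrane balances adsorption against
#' desorption: \code{k_a c_eq (1 - c_m/c_sat) = (k_d/2) c_m}, jointly with
#' phi-weighted mass conservation.  This reduces to a quadratic in
#' \code{c_m}; the root on \code{[0, c_sat]} is taken.
#'
#' @inheritParams simulate_kinetics
#' @return A \code{\link{compartment_state}}.
#' @export
equilibrium_state <- function(params, geometry, c_total) {
  if (!(params$k_d > 0)) stop("equilibrium requires k_d > 0")
  phi_aq <- geometry$phi_out + geometry$phi_in
  if (params$k_a == 0)
    return(compartment_state(c_o = c_total / phi_aq, c_m = 0,
                             c_i = c_total / phi_aq))
  K <- 2 * params$k_a / params$k_d           # linear partition coefficient
  if (!is.finite(params$c_sat)) {
    # linear regime: c_m = K c_eq
    c_eq <- c_total / (phi_aq + geometry$phi_mem * K)
    return(compartment_state(c_o = c_eq, c_m = K * c_eq, c_i = c_eq))
  }
  # K c_eq (1 - c_m/c_sat) = c_m with phi_aq c_eq + phi_mem c_m = c_total:
  # substitute c_eq and collect -> quadratic a c_m^2 + b c_m + c = 0
  # c_eq = (c_total - phi_mem c_m)/phi_aq
  # K (c_total - phi_mem c_m)(1 - c_m/c_sat) = phi_aq c_m
  # K c_total - K c_total c_m/c_sat - K phi_mem c_m + K phi_mem c_m^2/c_sat
  #   - phi_aq c_m = 0
  a <- K * geometry$phi_mem / params$c_sat
  b <- -(K * c_total / params$c_sat + K * geometry$phi_mem + phi_aq)
  cc <- K * c_total
  disc <- b^2 - 4 * a * cc
  c_m <- if (a > 0) (-b - sqrt(disc)) / (2 * a) else -cc / b
  c_m <- min(max(c_m, 0), params$c_sat)
  c_eq <- (c_total - geometry$phi_mem * c_m) / phi_aq
  compartment_state(c_o = c_eq, c_m = c_m, c_i = c_eq)
}

#' Normalized LUV-integrated uptake curve
#'
#' The experimentally observed quantity: the amount of polymer in or inside
#' the vesicles, normalized by its value at the last trajectory time,
#' \code{f(t) = [phi_mem c_m(t) + phi_in c_i(t)] / [phi_mem c_m(t_max) +
#' phi_in c_i(t_max)]}.
#'
#' @param traj A \code{\link{trajectory}}.
#' @return Numeric vector \code{f(t)} with \code{f(t_max) = 1}.
#' @export
integrated_fraction <- function(traj) {
  if (nrow(traj) < 2) stop("trajectory needs at least 2 points")
  g <- attr(traj, "geometry")
  amount <- g$phi_mem * traj$c_m + g$phi_in * traj$c_i
  denom <- amount[length(amount)]
  if (!(denom > 0)) stop("no uptake: LUV-integrated amount is zero at t_max")
  amount / denom
}

#' Limiting slopes of the two-step log curve
#'
#' Least-squares slopes of \code{ln(1 - f(t)/f(t_max))} over the initial and
#' terminal windows of the curve.  The initial slope magnitude grows with the
#' adsorption rate \code{k_a}, the terminal slope magnitude with the
#' desorption rate \code{k_d}; the crossover level reflects the membrane
#' saturation concentration.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param early,late Fractions of the finite-log points used for the initial
#'   and terminal fits (defaults 0.15 and 0.25).
#' @return List with \code{initial} and \code{terminal} slopes (1/s).
#' @export
limiting_slopes <- function(traj, early = 0.15, late = 0.25) {
  f <- integrated_fraction(traj)
  y <- suppressWarnings(log(1 - f))
  ok <- is.finite(y)
  if (any(!ok[-length(y)]))
    warning("non-finite log values before t_max excluded from the slope fits")
  t <- traj$time[ok]; y <- y[ok]
  n <- length(y)
  if (n < 10) stop("degenerate uptake curve: too few finite log points to resolve two regimes")
  n_e <- max(5L, ceiling(early * n))
  n_l <- max(5L, ceiling(late * n))
  fit <- function(tt, yy) unname(stats::coef(stats::lm(yy ~ tt))[2])
  list(initial = fit(t[seq_len(n_e)], y[seq_len(n_e)]),
       terminal = fit(t[seq.int(n - n_l + 1L, n)], y[seq.int(n - n_l + 1L, n)]))
}

# Avogadro constant (1/mol)
.N_A <- 6.02214076e23

#' Polymer molecules per vesicle
#'
#' Converts the membrane and inner-volume concentration trajectories to
#' absolute molecule counts per vesicle.  Concentrations are mass fractions
#' of an aqueous sample (density 1 g/mL assumed), compartment volumes are in
#' nm^3, molecular weight in kg/mol.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param mw Molecular weight in kg/mol.
#' @return Data frame with columns \code{time}, \code{n_mem}, \code{n_in}.
#' @export
molecules_per_vesicle <- function(traj, mw) {
  stopifnot(is.numeric(mw), mw > 0)
  g <- attr(traj, "geometry")
  if (!(g$n_ves > 0)) stop("geometry has no vesicles (n_ves = 0)")
  # mass fraction * (1 g/mL sample density) = g/mL = g/cm^3; 1 nm^3 = 1e-21 cm^3
  to_count <- function(conc, vol_nm3)
    conc * 1.0 * vol_nm3 * 1e-21 / (mw * 1000) * .N_A
  data.frame(time = traj$time,
             n_mem = to_count(traj$c_m, g$v_mem),
             n_in  = to_count(traj$c_i, g$v_in))
}

#' Effective translocation time
#'
#' First time at which the inner-vesicle concentration reaches
#' \code{(1 - 1/e)} of the outer concentration, located by bracketing on the
#' trajectory grid and linear interpolation of \code{c_i/c_o - (1-1/e)}
#' between the bracketing points.  If the threshold is not reached within
#' the grid the result is censored: the last grid time is returned as an
#' open lower bound with \code{censored = TRUE}.
#'
#' @param traj A \code{\link{trajectory}}.
#' @return List with \code{time} (s) and logical \code{censored}.
#' @export
translocation_time <- function(traj) {
  thr <- 1 - exp(-1)
  r <- ifelse(traj$c_o > 0, traj$c_i / traj$c_o, Inf)
  if (r[1] >= thr) stop("initial state already above the (1 - 1/e) threshold")
  idx <- which(r >= thr)
  if (length(idx) == 0)
    return(list(time = traj$time[nrow(traj)], censored = TRUE))
  i <- idx[1]
  g0 <- r[i - 1] - thr; g1 <- r[i] - thr
  tstar <- traj$time[i - 1] - g0 * (traj$time[i] - traj$time[i - 1]) / (g1 - g0)
  list(time = tstar, censored = FALSE)
}

#' Membrane/water partition coefficient at equilibrium
#'
#' The ratio \code{c_pm/c_po} of the equilibrium membrane concentration to
#' the equilibrium outer-solution concentration.
#'
#' @inheritParams simulate_kinetics
#' @return Single number, the partition coefficient.
#' @export
partition_coefficient <- function(params, geometry, c_total) {
  eq <- equilibrium_state(params, geometry, c_total)
  if (!(eq$c_o > 0)) return(NA_real_)
  eq$c_m / eq$c_o
}
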