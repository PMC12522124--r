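# Independent oracles used across the test files.  Each reimplements the
# checked quantity by a different algorithm than the package code.

# --- kinetics ---------------------------------------------------------------

# naive fixed-step RK4 integration of the three-compartment rate equations,
# written directly from the flux terms (no deSolve, no package RHS reuse)
rk4_trajectory <- function(params, geometry, c_total, t_end, h) {
  ka <- params$k_a; kd <- params$k_d; cs <- params$c_sat
  po <- geometry$phi_out; pm <- geometry$phi_mem; pin <- geometry$phi_in
  deriv <- function(y) {
    S <- if (is.finite(cs)) 1 - y[2] / cs else 1
    c(po = (pm / po) * (kd / 2 * y[2] - ka * y[1] * S),
      m = ka * (y[1] + y[3]) * S - kd * y[2],
      i = (pm / pin) * (kd / 2 * y[2] - ka * y[3] * S))
  }
  y <- c(c_total / po, 0, 0)
  n <- ceiling(t_end / h)
  out_t <- numeric(0); out_y <- NULL
  keep <- unique(c(seq(1, n, length.out = 50), n))
  keep_i <- 1L
  for (s in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (keep_i <= length(keep) && s == keep[keep_i]) {
      out_t <- c(out_t, s * h); out_y <- rbind(out_y, y)
      keep_i <- keep_i + 1L
    }
  }
  data.frame(time = out_t, c_o = out_y[, 1], c_m = out_y[, 2],
             c_i = out_y[, 3])
}

# phi-weighted sum of the three flux terms, written out symbolically
conservation_residual <- function(state, params, geometry) {
  ka <- params$k_a; kd <- params$k_d; cs <- params$c_sat
  S <- if (is.finite(cs)) 1 - state$c_m / cs else 1
  flux_o <- kd / 2 * state$c_m - ka * state$c_o * S   # per membrane volume
  flux_i <- kd / 2 * state$c_m - ka * state$c_i * S
  flux_m <- ka * (state$c_o + state$c_i) * S - kd * state$c_m
  geometry$phi_mem * (flux_o + flux_i + flux_m)
}

# --- reflectometry ----------------------------------------------------------

# Abeles transfer-matrix reflectivity: interface + propagation matrices,
# an algorithm independent of the Parratt recursion.  sld in A^-2.
matrix_reflectivity <- function(q, sld, thick, rough) {
  n <- length(sld)
  sapply(q, function(qq) {
    kz <- sqrt(as.complex((qq / 2)^2 - 4 * pi * (sld - sld[1])))
    M <- diag(2)
    for (j in seq_len(n - 1)) {
      r <- (kz[j] - kz[j + 1]) / (kz[j] + kz[j + 1]) *
        exp(-2 * kz[j] * kz[j + 1] * rough[j + 1]^2)
      t <- 2 * kz[j] / (kz[j] + kz[j + 1])
      I <- matrix(c(1, r, r, 1), 2, 2) / t
      if (j < n - 1) {
        P <- diag(c(exp(-1i * kz[j + 1] * thick[j + 1]),
                    exp(1i * kz[j + 1] * thick[j + 1])))
        M <- M %*% I %*% P
      } else M <- M %*% I
    }
    min(Mod(M[2, 1] / M[1, 1])^2, 1)
  })
}

fresnel_reflectivity <- function(q, rho1, rho2) {
  kz1 <- q / 2
  kz2 <- sqrt(as.complex((q / 2)^2 - 4 * pi * (rho2 - rho1)))
  Mod((kz1 - kz2) / (kz1 + kz2))^2
}

# random n-layer stack (materials with random SLD, thickness, roughness)
random_stack <- function(n_layers, seed) {
  set.seed(seed)
  mk <- function(i, sld) nr_layer(
    thickness = stats::runif(1, 10, 80),
    material = nr_material(paste0("m", i), sld),
    roughness = stats::runif(1, 0, 4))
  layers <- lapply(seq_len(n_layers), function(i)
    mk(i, stats::runif(1, -0.5, 6.4)))
  layers[[1]]$thickness <- 0
  layers[[n_layers]]$thickness <- 0
  slab_stack(layers)
}

# --- misc -------------------------------------------------------------------

# a standard geometry + parameters for quick tests
test_geometry <- function() vesicle_geometry(R = 44, d = 4, c_lipid = 20)
test_params <- function() kinetic_params(k_a = 0.05, k_d = 5e-4, c_sat = 0.02)

# stack slds/thicks/roughs extractor mirroring the internal layout
stack_arrays <- function(stack, contrast) {
  list(sld = sapply(stack$layers, mixed_sld, solvent = contrast,
                    polymer = stack$polymer) * 1e-6,
       thick = sapply(stack$layers, `[[`, "thickness"),
       rough = sapply(stack$layers, `[[`, "roughness"))
}
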