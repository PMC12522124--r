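test_that("effective SLD mixing follows the volume-fraction rule", {
  base <- nr_material("lipid", 6.9, 0.9)
  d2o <- get_material("D2O")
  aap <- get_material("AAP")
  l0 <- nr_layer(14, base)
  expect_equal(mixed_sld(l0, d2o, aap), 6.9)
  l1 <- nr_layer(14, base, phi_solvent = 1)
  expect_equal(mixed_sld(l1, d2o, aap), d2o$sld)
  l2 <- nr_layer(14, base, phi_solvent = 0.1, phi_polymer = 0.25)
  expect_equal(mixed_sld(l2, d2o, aap),
               0.65 * 6.9 + 0.1 * 6.36 + 0.25 * aap$sld, tolerance = 1e-14)
  expect_error(nr_layer(14, base, phi_solvent = 0.6, phi_polymer = 0.6),
               "exceed")
})

test_that("the SLD profile renders steps, conserves layer integrals and isolates contrast", {
  stk <- bilayer_stack(phi_polymer_tails = c(0.05, 0.2))
  d2o <- get_material("D2O"); h2o <- get_material("H2O")
  # zero roughness: exact steps at the layer values
  stk0 <- stk
  for (i in seq_along(stk0$layers)) stk0$layers[[i]]$roughness <- 0
  prof0 <- render_profile(stk0, d2o, z_step = 0.1)
  slds <- sapply(stk0$layers, mixed_sld, solvent = d2o, polymer = stk0$polymer)
  expect_equal(prof0$rho[1], slds[1])
  expect_equal(prof0$rho[nrow(prof0)], slds[length(slds)])
  # inside the thick tail layers the profile sits exactly on the slab value
  zmid <- 12 + 4 + 8 + 7   # middle of the inner tail layer
  expect_equal(prof0$rho[which.min(abs(prof0$z - zmid))], slds[5],
               tolerance = 1e-12)
  # quadrature: integral over a layer ~ thickness x effective SLD (small sigma)
  stk1 <- stk
  for (i in seq_along(stk1$layers)) stk1$layers[[i]]$roughness <- 1
  prof1 <- render_profile(stk1, d2o, z_step = 0.05)
  in_layer <- prof1$z >= 12 + 4 + 8 & prof1$z <= 12 + 4 + 8 + 14
  integral <- sum(prof1$rho[in_layer]) * 0.05
  expect_equal(integral, 14 * slds[5], tolerance = 0.02)
  # swapping D2O -> H2O changes only solvent-dependent regions
  pd <- render_profile(stk0, d2o, z_step = 0.1)
  ph <- render_profile(stk0, h2o, z_step = 0.1)
  tails <- pd$z > 12 + 4 + 8 + 1 & pd$z < 12 + 4 + 8 + 2 * 14 - 1
  expect_equal(pd$rho[tails], ph$rho[tails], tolerance = 1e-12)
  solvent_side <- pd$z > max(pd$z) - 5
  expect_true(all(abs(pd$rho[solvent_side] - ph$rho[solvent_side]) > 5))
})

test_that("reflectivity reproduces total reflection and the Fresnel closed form", {
  si <- get_material("Si"); d2o <- get_material("D2O")
  stk <- slab_stack(list(nr_layer(0, si), nr_layer(0, "solvent")))
  qc <- sqrt(16 * pi * (6.36e-6 - 2.07e-6))
  below <- reflectivity(stk, d2o, q = c(qc / 3, qc / 1.5))
  expect_equal(below$R, c(1, 1))
  q <- seq(0.02, 0.3, by = 0.02)
  rc <- reflectivity(stk, d2o, q)
  expect_equal(rc$R, Re(fresnel_reflectivity(q, 2.07e-6, 6.36e-6)),
               tolerance = 1e-10)
})

test_that("a contrast-free slab and zero-thickness layers are invisible", {
  si <- get_material("Si"); d2o <- get_material("D2O")
  q <- seq(0.01, 0.25, by = 0.01)
  base <- slab_stack(list(nr_layer(0, si),
                          nr_layer(30, nr_material("film", 4.0)),
                          nr_layer(0, "solvent")))
  R0 <- reflectivity(base, d2o, q)$R
  # contrast-free slab: a layer indistinguishable from the adjacent bulk
  # solvent adds no interface and leaves the curve untouched
  ghost <- slab_stack(list(nr_layer(0, si),
                           nr_layer(30, nr_material("film", 4.0)),
                           nr_layer(25, "solvent"),
                           nr_layer(0, "solvent")))
  expect_equal(reflectivity(ghost, d2o, q)$R / R0, rep(1, length(q)),
               tolerance = 1e-12)
  # zero-thickness layer of arbitrary SLD anywhere
  zt <- slab_stack(list(nr_layer(0, si),
                        nr_layer(0, nr_material("phantom", 1.23)),
                        nr_layer(30, nr_material("film", 4.0)),
                        nr_layer(0, "solvent")))
  expect_equal(reflectivity(zt, d2o, q)$R / R0, rep(1, length(q)),
               tolerance = 1e-10)
})

test_that("the Parratt engine agrees with the transfer-matrix oracle", {
  d2o <- get_material("D2O")
  q <- exp(seq(log(0.005), log(0.3), length.out = 60))
  for (seed in 1:5) {
    stk <- random_stack(6, seed = 100 + seed)
    arr <- stack_arrays(stk, d2o)
    R_pkg <- reflectivity(stk, d2o, q)$R
    R_mat <- matrix_reflectivity(q, arr$sld, arr$thick, arr$rough)
    expect_equal(R_pkg, R_mat, tolerance = 1e-10)
  }
})

test_that("internal contrasts fading out recovers the outermost Fresnel curve", {
  si <- get_material("Si"); d2o <- get_material("D2O")
  q <- seq(0.02, 0.25, by = 0.01)
  # internal layers whose SLD approaches the fronting: only the Si|solvent
  # contrast remains and the curve collapses onto its Fresnel form
  mk <- function(eps) slab_stack(list(
    nr_layer(0, si),
    nr_layer(25, nr_material("a", 2.07 + eps * 2)),
    nr_layer(40, nr_material("b", 2.07 - eps * 1.5)),
    nr_layer(0, "solvent")))
  R_eps <- reflectivity(mk(1e-6), d2o, q)$R
  R_fres <- Re(fresnel_reflectivity(q, 2.07e-6, 6.36e-6))
  expect_equal(R_eps, R_fres, tolerance = 1e-4)
})

test_that("micro-slicing the smoothed profile reproduces the roughness factors", {
  si <- get_material("Si"); d2o <- get_material("D2O")
  q <- seq(0.01, 0.2, by = 0.005)
  for (sig in c(3, 6)) {
    stk <- slab_stack(list(nr_layer(0, si),
                           nr_layer(60, nr_material("film", 4.5),
                                    roughness = sig),
                           nr_layer(0, "solvent", roughness = sig)))
    R_nc <- reflectivity(stk, d2o, q)$R
    prof <- render_profile(stk, d2o, z_step = 1, pad = 8 * sig)
    n <- nrow(prof)
    sliced <- slab_stack(lapply(seq_len(n), function(i)
      nr_layer(ifelse(i == 1 || i == n, 0, 1),
               nr_material(paste0("s", i), prof$rho[i]))))
    R_sl <- reflectivity(sliced, d2o, q)$R
    expect_equal(R_sl, R_nc, tolerance = 1e-3)
  }
})

test_that("joint residual is zero at truth, additive, and locally convex", {
  d2o <- get_material("D2O"); h2o <- get_material("H2O")
  stk <- bilayer_stack(phi_polymer_tails = c(0.05, 0.2))
  q <- seq(0.01, 0.2, by = 0.005)
  curves <- gen_reflectivity(stk, list(d2o, h2o), q, rel_noise = 0)
  expect_equal(joint_residual(stk, curves, list(d2o, h2o)), 0,
               tolerance = 1e-12)
  chi_d <- joint_residual(stk, curves[1], list(d2o))
  chi_h <- joint_residual(stk, curves[2], list(h2o))
  expect_equal(joint_residual(stk, curves, list(d2o, h2o)), chi_d + chi_h,
               tolerance = 1e-10)
  # perturbing a shared thickness strictly increases chi-square near optimum
  perturb <- function(dt) {
    s <- stk
    s$layers[[5]]$thickness <- s$layers[[5]]$thickness + dt
    joint_residual(s, curves, list(d2o, h2o))
  }
  expect_gt(perturb(0.5), 0)
  expect_gt(perturb(-0.5), 0)
  expect_gt(perturb(1.0), perturb(0.5))
})

test_that("polymer mass fractions aggregate thickness-weighted and solvent-free", {
  aap <- get_material("AAP")
  lipid <- get_material("POPC-d-tails")
  # no polymer anywhere -> 0%
  stk0 <- bilayer_stack(phi_polymer_tails = c(0, 0))
  expect_equal(polymer_mass_fraction(stk0, c(5, 6)), 0)
  # equal volume fractions, equal densities over one layer -> 50%
  mat <- nr_material("x", 6.9, mass_density = aap$mass_density)
  stk1 <- slab_stack(list(nr_layer(0, get_material("Si")),
                          nr_layer(14, mat, phi_polymer = 0.5),
                          nr_layer(0, "solvent")),
                     polymer = aap)
  expect_equal(polymer_mass_fraction(stk1, 2), 50, tolerance = 1e-12)
  # two layers with unequal thickness: hand-aggregated oracle
  stk2 <- slab_stack(list(nr_layer(0, get_material("Si")),
                          nr_layer(10, lipid, phi_polymer = 0.10),
                          nr_layer(20, lipid, phi_polymer = 0.30),
                          nr_layer(0, "solvent")),
                     polymer = aap)
  dp <- aap$mass_density; dl <- lipid$mass_density
  mass_p <- 10 * 0.10 * dp + 20 * 0.30 * dp
  mass_l <- 10 * 0.90 * dl + 20 * 0.70 * dl
  expect_equal(polymer_mass_fraction(stk2, c(2, 3)),
               100 * mass_p / (mass_p + mass_l), tolerance = 1e-12)
  expect_error(polymer_mass_fraction(stk2, 4), "solvent")
})

test_that("unknown materials are rejected with the known list", {
  expect_error(get_material("unobtainium"), "known materials")
})
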