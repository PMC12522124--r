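#' Material with a neutron scattering length density
#'
#' SLD is the number-density-weighted sum of nuclear scattering lengths,
#' \code{rho(z) = sum_j n_j b_j}; here it is carried in the conventional
#' units of 1e-6 Angstrom^-2.  A mass density enables mass-concentration
#' conversions.
#'
#' @param name Label.
#' @param sld Scattering length density in 1e-6 A^-2.
#' @param mass_density Mass density in g/cm^3 (optional, needed for
#'   composition extraction).
#' @return An object of class \code{nr_material}.
#' @export
nr_material <- function(name, sld, mass_density = NA_real_) {
  stopifnot(is.character(name), is.finite(sld))
  if (!is.na(mass_density) && !(mass_density > 0))
    stop("mass density must be positive when given")
  structure(list(name = name, sld = as.numeric(sld),
                 mass_density = as.numeric(mass_density)),
            class = "nr_material")
}

#' @export
print.nr_material <- function(x, ...) {
  cat(sprintf("<nr_material> %s: SLD = %g e-6/A^2, density = %s g/cm^3\n",
              x$name, x$sld,
              if (is.na(x$mass_density)) "n/a" else format(x$mass_density)))
  invisible(x)
}

#' Built-in materials table
#'
#' Literature-typical SLDs (1e-6 A^-2) and mass densities (g/cm^3) for the
#' substrate, solvents, tail-deuterated POPC regions and hydrogenous
#' polymers.  These are editable defaults, not measured constants: override
#' any entry with \code{\link{nr_material}}.
#'
#' @return Data frame with columns \code{name}, \code{sld},
#'   \code{mass_density}.
#' @export
nr_materials_table <- function() {
  data.frame(
    name = c("Si", "SiO2", "H2O", "D2O", "POPC-d-tails", "POPC-d-heads",
             "PEG", "PPG", "AAP"),
    sld = c(2.07, 3.47, -0.56, 6.36, 6.90, 6.20, 0.64, 0.34, 0.55),
    mass_density = c(2.33, 2.20, 1.00, 1.105, 0.90, 1.18, 1.13, 1.00, 1.10),
    stringsAsFactors = FALSE)
}

#' Look up a built-in material
#'
#' @param name Material name from \code{\link{nr_materials_table}}.
#' @return An \code{\link{nr_material}}.
#' @export
get_material <- function(name) {
  tab <- nr_materials_table()
  i <- match(name, tab$name)
  if (is.na(i))
    stop(sprintf("unknown material '%s'; known materials: %s",
                 name, paste(tab$name, collapse = ", ")))
  nr_material(tab$name[i], tab$sld[i], tab$mass_density[i])
}

#' Slab layer with solvent and polymer penetration
#'
#' @param thickness Layer thickness in Angstrom (ignored for the first and
#'   last layer of a stack, which are semi-infinite).
#' @param material An \code{\link{nr_material}}, or the string
#'   \code{"solvent"} for a layer made of the (contrast-dependent) solvent.
#' @param roughness Gaussian roughness (A) of the interface to the previous
#'   layer.
#' @param phi_solvent,phi_polymer Volume fractions of solvent and polymer
#'   mixed into the layer; their sum must not exceed 1.
#' @return An object of class \code{nr_layer}.
#' @export
nr_layer <- function(thickness, material, roughness = 0,
                     phi_solvent = 0, phi_polymer = 0) {
  stopifnot(thickness >= 0, roughness >= 0,
            phi_solvent >= 0, phi_polymer >= 0)
  if (phi_solvent + phi_polymer > 1 + 1e-12)
    stop("phi_solvent + phi_polymer must not exceed 1")
  if (!identical(material, "solvent") && !inherits(material, "nr_material"))
    stop("'material' must be an nr_material or the string \"solvent\"")
  structure(list(thickness = as.numeric(thickness), material = material,
                 roughness = as.numeric(roughness),
                 phi_solvent = as.numeric(phi_solvent),
                 phi_polymer = as.numeric(phi_polymer)),
            class = "nr_layer")
}

#' Slab stack
#'
#' An ordered list of \code{\link{nr_layer}}s from the incident medium to
#' the backing; the first and last layers are semi-infinite (their
#' thicknesses are ignored).  The canonical supported-bilayer stack is
#' Si | SiO2 | thin water | inner heads | inner tails | outer tails |
#' outer heads | (brush) | bulk solvent.
#'
#' @param layers List of \code{\link{nr_layer}}s (length >= 2).
#' @param polymer Optional \code{\link{nr_material}} used for the
#'   \code{phi_polymer} fractions of all layers.
#' @return An object of class \code{slab_stack}.
#' @export
slab_stack <- function(layers, polymer = NULL) {
  stopifnot(is.list(layers), length(layers) >= 2)
  if (!all(vapply(layers, inherits, logical(1), "nr_layer")))
    stop("all elements of 'layers' must be nr_layer objects")
  if (!is.null(polymer)) stopifnot(inherits(polymer, "nr_material"))
  has_poly <- any(vapply(layers, function(l) l$phi_polymer > 0, logical(1)))
  if (has_poly && is.null(polymer))
    stop("layers carry polymer fractions but no polymer material was given")
  structure(list(layers = layers, polymer = polymer), class = "slab_stack")
}

#' @export
print.slab_stack <- function(x, ...) {
  cat(sprintf("<slab_stack> %d layers%s\n", length(x$layers),
              if (is.null(x$polymer)) "" else paste0(", polymer = ", x$polymer$name)))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    nm <- if (identical(l$material, "solvent")) "solvent" else l$material$name
    semi <- i == 1 || i == length(x$layers)
    cat(sprintf("  [%d] %-14s t = %6s A, sigma = %4g A, phi_s = %.2f, phi_p = %.2f\n",
                i, nm, if (semi) "inf" else format(l$thickness),
                l$roughness, l$phi_solvent, l$phi_polymer))
  }
  invisible(x)
}

#' Effective SLD of a penetrated layer
#'
#' Volume-fraction mixing of the base material with solvent and polymer:
#' \code{rho_eff = (1 - phi_s - phi_p) rho_base + phi_s rho_solvent +
#' phi_p rho_polymer}.
#'
#' @param layer An \code{\link{nr_layer}}.
#' @param solvent The solvent \code{\link{nr_material}} (the contrast).
#' @param polymer The polymer \code{\link{nr_material}} (may be \code{NULL}
#'   when the layer carries no polymer).
#' @return Effective SLD in 1e-6 A^-2.
#' @export
mixed_sld <- function(layer, solvent, polymer = NULL) {
  if (layer$phi_solvent + layer$phi_polymer > 1 + 1e-12)
    stop("fraction sum exceeds 1")
  rho_base <- if (identical(layer$material, "solvent")) solvent$sld
              else layer$material$sld
  rho_p <- if (layer$phi_polymer > 0) {
    if (is.null(polymer)) stop("polymer fraction > 0 but no polymer material")
    polymer$sld
  } else 0
  (1 - layer$phi_solvent - layer$phi_polymer) * rho_base +
    layer$phi_solvent * solvent$sld + layer$phi_polymer * rho_p
}

# effective SLD vector (1e-6 A^-2) of every layer under a contrast
.stack_slds <- function(stack, contrast) {
  vapply(stack$layers, mixed_sld, numeric(1),
         solvent = contrast, polymer = stack$polymer)
}

#' Real-space SLD profile
#'
#' Renders the piecewise-constant effective SLDs of the stack smoothed by
#' error-function interfaces of the stated roughnesses.
#'
#' @param stack A \code{\link{slab_stack}}.
#' @param contrast Solvent \code{\link{nr_material}}.
#' @param z_step Grid spacing in A.
#' @param pad Distance (A) the grid extends into the semi-infinite media.
#' @return Data frame with columns \code{z} (A) and \code{rho}
#'   (1e-6 A^-2), of class \code{sld_profile}.
#' @export
render_profile <- function(stack, contrast, z_step = 0.5, pad = 30) {
  rho <- .stack_slds(stack, contrast)
  n <- length(rho)
  thick <- vapply(stack$layers, `[[`, numeric(1), "thickness")[-c(1, n)]
  rough <- vapply(stack$layers, `[[`, numeric(1), "roughness")[-1]
  zint <- c(0, cumsum(thick))             # interface positions
  for (j in seq_along(rough)) {
    adj <- c(if (j > 1) thick[j - 1], if (j <= length(thick)) thick[j])
    if (length(adj) && any(rough[j] > adj))
      warning(sprintf("roughness %g A at interface %d exceeds an adjacent thickness",
                      rough[j], j))
  }
  z <- seq(zint[1] - pad, zint[length(zint)] + pad, by = z_step)
  prof <- rep(rho[1], length(z))
  for (j in seq_along(zint)) {
    s <- rough[j]
    step <- if (s > 0) 0.5 * (1 + .erf((z - zint[j]) / (s * sqrt(2))))
            else as.numeric(z >= zint[j])
    prof <- prof + (rho[j + 1] - rho[j]) * step
  }
  structure(data.frame(z = z, rho = prof),
            class = c("sld_profile", "data.frame"))
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Reflectivity curve container
#'
#' @param q q_z grid in 1/A (positive increasing).
#' @param R Reflectivities.
#' @param dR Optional uncertainties.
#' @param contrast Contrast label, e.g. \code{"D2O"}.
#' @return An object of class \code{reflectivity_curve}.
#' @export
reflectivity_curve <- function(q, R, dR = NULL, contrast = "") {
  stopifnot(length(q) == length(R), all(q > 0))
  if (any(diff(q) <= 0)) stop("'q' must be strictly increasing")
  if (!is.null(dR)) stopifnot(length(dR) == length(q), all(dR > 0))
  structure(list(q = as.numeric(q), R = as.numeric(R), dR = dR,
                 contrast = contrast), class = "reflectivity_curve")
}

# Parratt recursion with Nevot-Croce roughness factors.
# sld in A^-2 (absolute), thick/rough in A, q in 1/A. Returns |r|^2.
.parratt <- function(q, sld, thick, rough) {
  n <- length(sld)
  sapply(q, function(qq) {
    kz0 <- qq / 2
    kz <- sqrt(as.complex(kz0^2 - 4 * pi * (sld - sld[1])))
    # Fresnel coefficients with Nevot-Croce damping at each interface
    r <- (kz[-n] - kz[-1]) / (kz[-n] + kz[-1]) *
      exp(-2 * kz[-n] * kz[-1] * rough[-1]^2)
    R <- r[n - 1]
    if (n > 2) for (j in seq.int(n - 2, 1)) {
      ph <- exp(2i * kz[j + 1] * thick[j + 1])
      R <- (r[j] + R * ph) / (1 + r[j] * R * ph)
    }
    min(Mod(R)^2, 1)
  })
}

#' Specular reflectivity of a slab stack
#'
#' Parratt recursion over the effective-SLD slabs with Nevot-Croce
#' roughness factors, optionally smeared with a Gaussian q-resolution of
#' constant relative width (FWHM \code{dq_q}).
#'
#' @param stack A \code{\link{slab_stack}}.
#' @param contrast Solvent \code{\link{nr_material}}.
#' @param q q_z grid in 1/A (positive increasing).
#' @param dq_q Relative resolution FWHM Delta-q/q; 0 disables smearing.
#' @param n_smear Quadrature points for the resolution convolution.
#' @return A \code{\link{reflectivity_curve}}.
#' @examples
#' stk <- slab_stack(list(nr_layer(0, get_material("Si")),
#'                        nr_layer(0, "solvent")))
#' rc <- reflectivity(stk, get_material("D2O"), q = seq(0.005, 0.2, 0.005))
#' @export
reflectivity <- function(stack, contrast, q, dq_q = 0, n_smear = 17) {
  stopifnot(all(q > 0))
  rho <- .stack_slds(stack, contrast) * 1e-6
  thick <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  rough <- vapply(stack$layers, `[[`, numeric(1), "roughness")
  if (any(thick < 0)) stop("negative layer thickness")
  if (dq_q <= 0) {
    R <- .parratt(q, rho, thick, rough)
  } else {
    sd_rel <- dq_q / (2 * sqrt(2 * log(2)))
    u <- seq(-3, 3, length.out = n_smear)
    w <- stats::dnorm(u); w <- w / sum(w)
    R <- sapply(q, function(qq) {
      qs <- qq * (1 + sd_rel * u)
      qs <- pmax(qs, 1e-6)
      sum(w * .parratt(qs, rho, thick, rough))
    })
  }
  reflectivity_curve(q, R, contrast = contrast$name)
}

#' Joint chi-square of a stack against measured contrasts
#'
#' Sum over curves of \code{sum(((R_model - R)/dR)^2)}; with no \code{dR}
#' a 1 percent relative uncertainty floor is used.  The stack's structural
#' parameters are shared across contrasts; only the solvent SLD changes.
#'
#' @param stack A \code{\link{slab_stack}}.
#' @param curves List of \code{\link{reflectivity_curve}}s.
#' @param contrasts List of solvent \code{\link{nr_material}}s, one per
#'   curve (matched by position).
#' @param dq_q Resolution passed to \code{\link{reflectivity}}.
#' @return Total chi-square (single number).
#' @export
joint_residual <- function(stack, curves, contrasts, dq_q = 0) {
  stopifnot(length(curves) == length(contrasts))
  total <- 0
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    mod <- reflectivity(stack, contrasts[[i]], cv$q, dq_q = dq_q)
    dR <- if (!is.null(cv$dR)) cv$dR else pmax(0.01 * cv$R, 1e-12)
    total <- total + sum(((mod$R - cv$R) / dR)^2)
  }
  total
}

#' Polymer mass concentration of a membrane region
#'
#' Thickness-weighted mass fraction of polymer relative to polymer plus
#' base (lipid) material over the selected layers,
#' \code{100 * sum(t phi_p d_p) / sum(t (phi_p d_p + phi_base d_base))}
#' with \code{phi_base = 1 - phi_s - phi_p}.  Solvent is excluded from the
#' mass basis by default (polymer relative to polymer + lipid);
#' \code{include_solvent = TRUE} adds the solvent mass using its material
#' density.
#'
#' @param stack A \code{\link{slab_stack}} whose \code{polymer} material has
#'   a mass density.
#' @param region Integer indices of the layers to aggregate (e.g. the two
#'   tail layers).
#' @param include_solvent Logical; include solvent in the mass basis.
#' @param solvent Solvent \code{\link{nr_material}} (only needed with
#'   \code{include_solvent = TRUE}).
#' @return Mass concentration in percent.
#' @export
polymer_mass_fraction <- function(stack, region, include_solvent = FALSE,
                                  solvent = NULL) {
  stopifnot(all(region >= 1), all(region <= length(stack$layers)))
  if (is.null(stack$polymer) || is.na(stack$polymer$mass_density))
    stop("stack polymer material with a mass density is required")
  d_p <- stack$polymer$mass_density
  mass_p <- 0; mass_tot <- 0
  for (i in region) {
    l <- stack$layers[[i]]
    if (identical(l$material, "solvent"))
      stop("region includes a pure-solvent layer; composition undefined there")
    d_base <- l$material$mass_density
    if (is.na(d_base)) stop(sprintf("layer %d base material lacks a mass density", i))
    t <- l$thickness
    phi_base <- 1 - l$phi_solvent - l$phi_polymer
    mp <- t * l$phi_polymer * d_p
    mtot <- mp + t * phi_base * d_base
    if (include_solvent) {
      if (is.null(solvent) || is.na(solvent$mass_density))
        stop("include_solvent = TRUE needs a solvent material with density")
      mtot <- mtot + t * l$phi_solvent * solvent$mass_density
    }
    mass_p <- mass_p + mp
    mass_tot <- mass_tot + mtot
  }
  if (!(mass_tot > 0)) stop("zero total mass basis in the selected region")
  100 * mass_p / mass_tot
}

#' Canonical supported-bilayer stack
#'
#' Convenience constructor for the Si | SiO2 | thin water | inner heads |
#' inner tails | outer tails | outer heads | (brush) | solvent stack with
#' per-layer polymer/solvent penetration.
#'
#' @param sio2 Thickness (A) of the native oxide.
#' @param water Thickness (A) of the thin water cushion.
#' @param heads,tails Thicknesses (A) of each headgroup and tail layer.
#' @param roughness Common interfacial roughness (A).
#' @param phi_head_solvent Solvent fraction of the headgroup layers.
#' @param phi_polymer_tails Named or length-2 vector: polymer fraction in
#'   the (inner, outer) tail layers.
#' @param phi_polymer_heads Polymer fraction in the (inner, outer)
#'   headgroup layers.
#' @param brush Optional list(thickness, phi_polymer) for an outer polymer
#'   brush layer (solvent fills the rest).
#' @param polymer Polymer \code{\link{nr_material}}.
#' @param heads_material,tails_material Lipid region materials.
#' @return A \code{\link{slab_stack}}.
#' @export
bilayer_stack <- function(sio2 = 12, water = 4, heads = 8, tails = 14,
                          roughness = 3, phi_head_solvent = 0.3,
                          phi_polymer_tails = c(0, 0),
                          phi_polymer_heads = c(0, 0),
                          brush = NULL, polymer = get_material("AAP"),
                          heads_material = get_material("POPC-d-heads"),
                          tails_material = get_material("POPC-d-tails")) {
  layers <- list(
    nr_layer(0, get_material("Si")),
    nr_layer(sio2, get_material("SiO2"), roughness = 2),
    nr_layer(water, "solvent", roughness = roughness),
    nr_layer(heads, heads_material, roughness = roughness,
             phi_solvent = phi_head_solvent,
             phi_polymer = phi_polymer_heads[1]),
    nr_layer(tails, tails_material, roughness = roughness,
             phi_polymer = phi_polymer_tails[1]),
    nr_layer(tails, tails_material, roughness = roughness,
             phi_polymer = phi_polymer_tails[2]),
    nr_layer(heads, heads_material, roughness = roughness,
             phi_solvent = phi_head_solvent,
             phi_polymer = phi_polymer_heads[2]))
  if (!is.null(brush))
    layers <- c(layers, list(nr_layer(brush$thickness, "solvent",
                                      roughness = roughness,
                                      phi_polymer = brush$phi_polymer)))
  layers <- c(layers, list(nr_layer(0, "solvent", roughness = roughness)))
  slab_stack(layers, polymer = polymer)
}
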