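#' Polymer descriptor
#'
#' Describes an alternating amphiphilic polymer (AAP) built from hydrophobic
#' dicarboxylic-acid units with \code{m} backbone carbons and hydrophilic
#' oligo(ethylene glycol) units of \code{n} EG monomers, or a triblock
#' copolymer (e.g. PEG-PPG-PEG) for which the alternating unit structure does
#' not apply.
#'
#' @param name Label, e.g. \code{"P(C4EG4)2k"}.
#' @param m Integer, carbons per diacid unit (ignored for triblocks).
#' @param n Integer, EG monomers per hydrophilic unit (ignored for triblocks).
#' @param mw Molecular weight in kg/mol.
#' @param lcst Lower critical solution temperature in degrees C, or \code{NA}.
#' @param triblock Logical; \code{TRUE} for block architectures, in which case
#'   \code{m} and \code{n} may be \code{NA}.
#' @return An object of class \code{polymer_spec}.
#' @examples
#' polymer_spec("P(C4EG4)2k", m = 4, n = 4, mw = 2, lcst = 26)
#' polymer_spec("Pluronic-F127", mw = 12.6, triblock = TRUE)
#' @export
polymer_spec <- function(name, m = NA_integer_, n = NA_integer_, mw,
                         lcst = NA_real_, triblock = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(m)) m <- NA_integer_
  if (is.null(n)) n <- NA_integer_
  if (!triblock) {
    if (is.na(m) || is.na(n))
      stop("alternating polymers need both 'm' and 'n'; use triblock = TRUE otherwise")
    if (m < 0 || n < 0) stop("'m' and 'n' must be non-negative integers")
  }
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop("'mw' must be a single positive number (kg/mol)")
  structure(list(name = name, m = as.integer(m), n = as.integer(n),
                 mw = as.numeric(mw), lcst = as.numeric(lcst),
                 triblock = isTRUE(triblock)),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  arch <- if (x$triblock) "triblock" else sprintf("P(C%dEG%d)", x$m, x$n)
  cat(sprintf("<polymer_spec> %s [%s], MW = %g kg/mol, LCST = %s degC\n",
              x$name, arch, x$mw,
              if (is.na(x$lcst)) "n/a" else format(x$lcst)))
  invisible(x)
}

#' Vesicle suspension geometry
#'
#' Derives the compartment volume fractions of a monodisperse large
#' unilamellar vesicle (LUV) suspension from the vesicle outer radius, the
#' bilayer thickness and the lipid loading.  The membrane volume fraction is
#' identified with the lipid volume fraction \code{c_lipid / rho_lipid};
#' the vesicle number density follows as \code{phi_mem / v_mem} and the inner
#' volume fraction as \code{n_ves * v_in}.
#'
#' @param R Outer vesicle radius in nm.
#' @param d Bilayer thickness in nm; must satisfy \code{0 < d < R}.
#' @param c_lipid Lipid mass concentration in mg/mL.
#' @param rho_lipid Lipid mass density in g/mL (default 1.0).
#' @return An object of class \code{vesicle_geometry} with elements
#'   \code{R}, \code{d}, \code{v_in}, \code{v_mem} (nm^3 per vesicle),
#'   \code{phi_in}, \code{phi_mem}, \code{phi_out} (volume fractions summing
#'   to 1) and \code{n_ves} (vesicles per nm^3 of sample).
#' @examples
#' geom <- vesicle_geometry(R = 44, d = 4, c_lipid = 20)
#' geom$phi_mem  # 0.02 for 20 mg/mL lipid at density 1 g/mL
#' @export
vesicle_geometry <- function(R, d, c_lipid, rho_lipid = 1.0) {
  stopifnot(is.numeric(R), is.numeric(d), is.numeric(c_lipid),
            is.numeric(rho_lipid))
  if (!(d > 0) || !(d < R)) stop("need 0 < d < R (bilayer thinner than vesicle)")
  if (c_lipid < 0 || rho_lipid <= 0) stop("lipid concentration/density must be positive")
  phi_mem <- (c_lipid / 1000) / rho_lipid   # mg/mL over g/mL -> volume fraction
  if (phi_mem >= 1) stop("lipid volume fraction >= 1: over-concentrated suspension")
  v_in  <- (4 / 3) * pi * (R - d)^3
  v_mem <- (4 / 3) * pi * (R^3 - (R - d)^3)
  n_ves <- if (phi_mem > 0) phi_mem / v_mem else 0
  phi_in  <- n_ves * v_in
  phi_out <- 1 - phi_in - phi_mem
  if (phi_out <= 0)
    stop("phi_out <= 0: suspension too concentrated for the closed-vesicle model")
  structure(list(R = R, d = d, c_lipid = c_lipid, rho_lipid = rho_lipid,
                 v_in = v_in, v_mem = v_mem, n_ves = n_ves,
                 phi_in = phi_in, phi_mem = phi_mem, phi_out = phi_out),
            class = "vesicle_geometry")
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat(sprintf("<vesicle_geometry> R = %g nm, d = %g nm\n", x$R, x$d))
  cat(sprintf("  phi_out = %.6g, phi_mem = %.6g, phi_in = %.6g\n",
              x$phi_out, x$phi_mem, x$phi_in))
  cat(sprintf("  v_in = %.6g nm^3, v_mem = %.6g nm^3, n_ves = %.6g /nm^3\n",
              x$v_in, x$v_mem, x$n_ves))
  invisible(x)
}
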