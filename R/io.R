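#' Read a kinetic trace from delimited text
#'
#' Expects a header line and columns \code{time_s}, \code{intensity} and
#' optionally \code{sigma} (whitespace-, comma- or tab-delimited).  Times
#' may alternatively be given as \code{time_min}, in which case they are
#' converted to seconds.
#'
#' @param path File path.
#' @return A \code{\link{kinetic_trace}}.
#' @export
read_kinetic_trace <- function(path) {
  df <- .read_table(path)
  tcol <- intersect(c("time_s", "time_min"), names(df))
  if (length(tcol) == 0 || !"intensity" %in% names(df))
    stop(sprintf("'%s': need columns time_s (or time_min) and intensity; found: %s",
                 path, paste(names(df), collapse = ", ")))
  times <- if (tcol[1] == "time_min") df[[tcol[1]]] * 60 else df[[tcol[1]]]
  kinetic_trace(times, df$intensity,
                sigma = if ("sigma" %in% names(df)) df$sigma else NULL)
}

#' Write a kinetic trace
#'
#' @param trace A \code{\link{kinetic_trace}}.
#' @param path Output file path.
#' @export
write_kinetic_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$times, intensity = trace$intensity)
  if (!is.null(trace$sigma)) df$sigma <- trace$sigma
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an echo decay (q^2, intensity[, error]) file
#'
#' Columns \code{q2}, \code{intensity} and optionally \code{error}.
#'
#' @param path File path.
#' @return An \code{\link{echo_decay}}.
#' @export
read_echo_decay <- function(path) {
  df <- .read_table(path)
  if (!all(c("q2", "intensity") %in% names(df)))
    stop(sprintf("'%s': need columns q2 and intensity", path))
  echo_decay(df$q2, df$intensity,
             errors = if ("error" %in% names(df)) df$error else NULL)
}

#' Write an echo decay
#' @param decay An \code{\link{echo_decay}}.
#' @param path Output file path.
#' @export
write_echo_decay <- function(decay, path) {
  df <- data.frame(q2 = decay$q2, intensity = decay$intensity)
  if (!is.null(decay$errors)) df$error <- decay$errors
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reflectivity curve (q, R[, dR]) file
#'
#' Two or three whitespace/comma/tab-separated columns, with or without a
#' header line (\code{q}, \code{R}, \code{dR}).
#'
#' @param path File path.
#' @param contrast Contrast label stored on the curve.
#' @return A \code{\link{reflectivity_curve}}.
#' @export
read_reflectivity <- function(path, contrast = "") {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- .read_table(path, header = has_header)
  if (!has_header) names(df) <- c("q", "R", "dR")[seq_len(ncol(df))]
  if (!all(c("q", "R") %in% names(df)))
    stop(sprintf("'%s': need columns q and R", path))
  reflectivity_curve(df$q, df$R,
                     dR = if ("dR" %in% names(df)) df$dR else NULL,
                     contrast = contrast)
}

#' Write a reflectivity curve
#' @param curve A \code{\link{reflectivity_curve}}.
#' @param path Output file path.
#' @export
write_reflectivity <- function(curve, path) {
  df <- data.frame(q = curve$q, R = curve$R)
  if (!is.null(curve$dR)) df$dR <- curve$dR
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory with derived observables
#'
#' Writes the documented trajectory dialect: columns \code{time_s},
#' \code{c_o}, \code{c_m}, \code{c_i}, \code{f} (normalized integrated
#' fraction) and, when a molecular weight is available, the per-vesicle
#' counts \code{n_mem_per_vesicle} and \code{n_in_per_vesicle}.
#'
#' @param traj A \code{\link{trajectory}}.
#' @param path Output file path.
#' @param mw Molecular weight in kg/mol (optional).
#' @export
write_trajectory <- function(traj, path, mw = NULL) {
  df <- data.frame(time_s = traj$time, c_o = traj$c_o, c_m = traj$c_m,
                   c_i = traj$c_i, f = integrated_fraction(traj))
  if (!is.null(mw)) {
    counts <- molecules_per_vesicle(traj, mw)
    df$n_mem_per_vesicle <- counts$n_mem
    df$n_in_per_vesicle <- counts$n_in
  }
  utils::write.table(format(df, digits = 15), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# tolerant delimited reader: tab, comma or whitespace
.read_table <- function(path, header = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep,
                      strip.white = TRUE, comment.char = "#"),
    error = function(e)
      stop(sprintf("parse error in '%s': %s", path, conditionMessage(e))))
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) && header)
    stop(sprintf("parse error in '%s': non-numeric values in column(s) %s",
                 path, paste(names(df)[bad], collapse = ", ")))
  df
}

#' Read a run configuration
#'
#' A single structured YAML text file with blocks \code{geometry}
#' (\code{R_nm}, \code{d_nm}, \code{lipid_mg_per_ml},
#' \code{lipid_density_g_per_ml}), \code{polymer} (\code{name}, \code{m},
#' \code{n}, \code{mw_kg_mol}, \code{lcst_C}, \code{triblock}),
#' \code{kinetics} (\code{k_a}, \code{k_d}, \code{c_sat}),
#' \code{c_polymer_wt_percent} and \code{seed}.  Missing required keys are
#' reported by name.
#'
#' @param path File path.
#' @return An object of class \code{run_config} (named list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as boolean FALSE; restore the EG-unit key
  if (!is.null(cfg$polymer))
    names(cfg$polymer)[names(cfg$polymer) == "FALSE"] <- "n"
  for (key in c("geometry", "polymer"))
    if (is.null(cfg[[key]]))
      stop(sprintf("config '%s': missing required block '%s'", path, key))
  for (key in c("R_nm", "d_nm", "lipid_mg_per_ml"))
    if (is.null(cfg$geometry[[key]]))
      stop(sprintf("config '%s': missing geometry key '%s'", path, key))
  if (is.null(cfg$polymer$mw_kg_mol))
    stop(sprintf("config '%s': missing polymer key 'mw_kg_mol'", path))
  structure(cfg, class = "run_config")
}

# build package objects from a parsed config
.config_geometry <- function(cfg)
  vesicle_geometry(cfg$geometry$R_nm, cfg$geometry$d_nm,
                   cfg$geometry$lipid_mg_per_ml,
                   rho_lipid = cfg$geometry$lipid_density_g_per_ml %||% 1.0)

.config_polymer <- function(cfg)
  polymer_spec(cfg$polymer$name %||% "polymer",
               m = cfg$polymer$m %||% NA_integer_,
               n = cfg$polymer$n %||% NA_integer_,
               mw = cfg$polymer$mw_kg_mol,
               lcst = cfg$polymer$lcst_C %||% NA_real_,
               triblock = isTRUE(cfg$polymer$triblock))

.config_params <- function(cfg) {
  k <- cfg$kinetics
  if (is.null(k)) stop("config: missing 'kinetics' block (k_a, k_d, c_sat)")
  for (key in c("k_a", "k_d", "c_sat"))
    if (is.null(k[[key]])) stop(sprintf("config: missing kinetics key '%s'", key))
  kinetic_params(k$k_a, k$k_d, k$c_sat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# provenance record written next to every run output
.write_provenance <- function(dir, cfg, seed, command) {
  rec <- list(command = command, seed = seed,
              package = "luvtrans",
              version = as.character(utils::packageVersion("luvtrans")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"),
              config = unclass(cfg))
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a forward kinetic simulation from a config
#'
#' Simulates the configured scenario, writes the trajectory export, a
#' noise-free model trace, a noisy synthetic trace at the configured noise
#' level, and a provenance record into \code{out_dir}.
#'
#' @param config Path to a config file or a \code{run_config} list.
#' @param out_dir Output directory (created if needed).
#' @param n_points Time points of the synthetic trace.
#' @return Invisibly, a list of written file paths.
#' @export
run_simulate <- function(config, out_dir, n_points = 100) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- .config_geometry(cfg)
  params <- .config_params(cfg)
  poly <- .config_polymer(cfg)
  c_total <- (cfg$c_polymer_wt_percent %||% 1) / 100
  seed <- cfg$seed %||% 1L
  scn <- scenario("config-run", geom, params, poly, c_total,
                  sigma = cfg$sigma %||% 0.02, seed = seed)
  trace <- gen_kinetic_trace(scn, n_points = n_points)
  traj <- simulate_kinetics(params, geom, c_total, trace$times)
  paths <- list(trajectory = file.path(out_dir, "trajectory.tsv"),
                trace = file.path(out_dir, "trace.tsv"))
  write_trajectory(traj, paths$trajectory, mw = poly$mw)
  write_kinetic_trace(trace, paths$trace)
  .write_provenance(out_dir, cfg, seed, "simulate")
  invisible(paths)
}

#' Fit a kinetic trace from a config
#'
#' Reads the trace named in \code{config$trace_file} (or takes \code{trace}
#' directly), runs the ensemble MCMC and writes a JSON fit report with
#' point estimates, credible intervals, diagnostics and the seed.
#'
#' @param config Path or \code{run_config}; kinetics block optional here.
#' @param out_dir Output directory.
#' @param trace Optional \code{\link{kinetic_trace}} overriding
#'   \code{config$trace_file}.
#' @param n_walkers,n_steps,burn_in Sampler settings.
#' @return Invisibly, the \code{\link{posterior_summary}}.
#' @export
run_fit <- function(config, out_dir, trace = NULL, n_walkers = 24,
                    n_steps = 600, burn_in = 0.3) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (burn_in >= 1 && burn_in >= n_steps)
    stop("burn_in must be smaller than n_steps")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- .config_geometry(cfg)
  c_total <- (cfg$c_polymer_wt_percent %||% 1) / 100
  seed <- cfg$seed %||% 1L
  if (is.null(trace)) {
    if (is.null(cfg$trace_file)) stop("config: missing 'trace_file'")
    trace <- read_kinetic_trace(cfg$trace_file)
  }
  post <- fit_mcmc(trace, prior_spec(), geom, c_total,
                   n_walkers = n_walkers, n_steps = n_steps, seed = seed)
  sm <- posterior_summary(post, burn_in = burn_in)
  report <- list(estimates = sm$table, map = as.list(sm$map),
                 rhat = as.list(sm$rhat), acceptance = sm$acceptance,
                 n_samples = sm$n_samples, seed = seed)
  jsonlite::write_json(report, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_provenance(out_dir, cfg, seed, "fit")
  invisible(sm)
}

#' Forward reflectometry run from a stack
#'
#' Computes reflectivity curves for the given contrasts, the SLD profiles,
#' and a per-region composition report, writing each as delimited text or
#' JSON into \code{out_dir}.
#'
#' @param stack A \code{\link{slab_stack}}.
#' @param contrasts List of solvent \code{\link{nr_material}}s.
#' @param q q_z grid (1/A).
#' @param out_dir Output directory.
#' @param regions Named list of integer layer-index vectors for the
#'   composition report (e.g. \code{list(tails = c(5, 6))}).
#' @param dq_q Resolution FWHM.
#' @return Invisibly, the composition report (named list of mass percents).
#' @export
run_nr <- function(stack, contrasts, q, out_dir, regions = list(),
                   dq_q = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in contrasts) {
    rc <- reflectivity(stack, ct, q, dq_q = dq_q)
    write_reflectivity(rc, file.path(out_dir, sprintf("refl_%s.tsv", ct$name)))
    prof <- render_profile(stack, ct)
    utils::write.table(format(prof, digits = 10),
                       file.path(out_dir, sprintf("sld_%s.tsv", ct$name)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  comp <- lapply(regions, function(idx) polymer_mass_fraction(stack, idx))
  if (length(comp))
    jsonlite::write_json(comp, file.path(out_dir, "composition.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(comp)
}
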