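# Configuration, serialization and fixtures: a declarative YAML config with
# sections electrolyte / protein / graphene / adsorption / stack / grid /
# sweep / noise, schema-validated with defaults materialized so every output
# is self-describing. A single seeded pseudo-random stream (noise$seed) owns
# all randomness in the pipeline.

.unit_factors <- list(
  "m" = 1, "nm" = 1e-9, "um" = 1e-6, "mm" = 1e-3, "A" = 1e-10,
  "g/L" = 1, "mg/L" = 1e-3,
  "mol/m^3" = 1, "mM" = 1, "M" = 1e3,
  "s" = 1, "fs" = 1e-15, "ps" = 1e-12,
  "eV" = 1, "K" = 1, "THz" = 1, "m/s" = 1)

# Parse "1.18 g/L" / "0.5 nm" style strings into the canonical unit of the
# field; plain numerics pass through unchanged (assumed canonical).
.parse_quantity <- function(x, canonical, key) {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1L)
    stop(sprintf("config key '%s': expected a number (unit %s) or a \"<value> <unit>\" string",
                 key, canonical), call. = FALSE)
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  val <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(val))
    stop(sprintf("config key '%s': cannot parse value from '%s'", key, x), call. = FALSE)
  if (length(parts) == 1L) return(val)
  unit <- parts[2]
  if (is.null(.unit_factors[[unit]]))
    stop(sprintf("config key '%s': unknown unit '%s' (expected %s)", key, unit,
                 canonical), call. = FALSE)
  to <- .unit_factors[[canonical]]
  val * .unit_factors[[unit]] / to
}

#' Default model configuration
#'
#' All tunable parameters of the pipeline with their default values, in the
#' canonical units noted per key. The defaults describe the shipped
#' operating point: a 1 mM aqueous electrolyte at 300 K, the
#' beta-2-microglobulin analyte constants, a graphene baseline doping of
#' 0.3 eV (the absorber's optimal level), a Langmuir adsorption isotherm,
#' and an absorber stack electrolyte / graphene / SiO2-like spacer
#' (eps 3.9, 10 um) / graphene / PEC whose resonance falls at 3-4 THz,
#' on the rising branch of the resonance-vs-gating curve where including
#' the quantum capacitance strictly enlarges the concentration response.
#'
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    electrolyte = list(
      c_salt = 1,          # mol/m^3
      z_salt = 1,
      eps_r = 78.5,
      eps_H = 6,
      d_H = 0.5e-9,        # m
      T = 300,             # K
      eps_H2O = 78.5,
      A_DF = 0.12          # permittivity per sqrt(mol/m^3)
    ),
    protein = list(
      z_p = -2,
      diameter = 4e-9,     # m
      D_p = 1.35e-10,      # m^2/s (0.0135 A^2/ps)
      molar_mass = 11800,  # g/mol
      c_bulk = 0           # g/L
    ),
    graphene = list(
      v_f = 1e6,           # m/s (reproduces the 1.16e-7 eV cm gating prefactor)
      tau = 1e-13,         # s
      T = 300,             # K
      E_f_baseline = 0.3,  # eV, optimal absorber doping
      interband_form = "standard"
    ),
    adsorption = list(
      kind = "langmuir",
      K_ads = 10,          # L/g
      Gamma_max = 1e16,    # m^-2
      n0 = NA              # m^-2; NA -> density at E_f_baseline
    ),
    stack = list(
      eps_H2O_optical = 4.2,   # water permittivity in the THz band
      spacer_eps = 3.9,
      spacer_thickness = 10e-6, # m
      backing = "PEC"
    ),
    grid = list(
      f_min = 0.1,         # THz
      f_max = 10,          # THz
      n_f = 2000
    ),
    sweep = list(
      concentrations = c(0.00118, 0.0118, 0.118, 1.18)  # g/L
    ),
    noise = list(
      seed = 1,
      amplitude = 1e-3,
      n_reps = 25
    )
  ), class = "run_config")
}

# Recursive merge of user values over defaults, rejecting unknown keys.
.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    kp <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(defaults))
      stop(sprintf("unknown config key '%s'", kp), call. = FALSE)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop(sprintf("config key '%s' must be a section", kp), call. = FALSE)
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], kp)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

# Validate and normalize a merged config: parse unit strings, check
# positivity, resolve derived defaults (n0), attach spec objects.
.validate_config <- function(cfg) {
  cfg$protein$c_bulk <- .parse_quantity(cfg$protein$c_bulk, "g/L", "protein$c_bulk")
  cfg$electrolyte$d_H <- .parse_quantity(cfg$electrolyte$d_H, "m", "electrolyte$d_H")
  cfg$protein$diameter <- .parse_quantity(cfg$protein$diameter, "m", "protein$diameter")
  cfg$stack$spacer_thickness <- .parse_quantity(cfg$stack$spacer_thickness, "m",
                                                "stack$spacer_thickness")
  pos_keys <- list(
    c("electrolyte", "c_salt"), c("electrolyte", "eps_r"), c("electrolyte", "eps_H"),
    c("electrolyte", "d_H"), c("electrolyte", "T"), c("electrolyte", "eps_H2O"),
    c("protein", "diameter"), c("protein", "D_p"), c("protein", "molar_mass"),
    c("graphene", "v_f"), c("graphene", "tau"), c("graphene", "T"),
    c("adsorption", "K_ads"), c("adsorption", "Gamma_max"),
    c("stack", "spacer_eps"), c("stack", "spacer_thickness"),
    c("grid", "f_min"), c("grid", "f_max"), c("grid", "n_f"))
  for (pk in pos_keys) {
    v <- cfg[[pk[1]]][[pk[2]]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("config key '%s$%s' must be a positive number (SI units)",
                   pk[1], pk[2]), call. = FALSE)
  }
  if (cfg$protein$c_bulk < 0)
    stop("config key 'protein$c_bulk' must be >= 0 (g/L)", call. = FALSE)
  if (cfg$grid$f_max <= cfg$grid$f_min)
    stop("config key 'grid$f_max' must exceed 'grid$f_min' (THz)", call. = FALSE)
  if (is.na(cfg$adsorption$n0) || is.null(cfg$adsorption$n0))
    cfg$adsorption$n0 <- density_for_fermi_energy(cfg$graphene$E_f_baseline,
                                                  cfg$graphene$v_f)
  cfg
}

# Attach constructed spec objects (idempotent); internal.
.materialize_config <- function(cfg) {
  if (!is.null(cfg$electrolyte_obj)) return(cfg)
  cfg <- .validate_config(unclass(cfg))
  e <- cfg$electrolyte
  cfg$electrolyte_obj <- electrolyte_spec(e$c_salt, e$z_salt, e$eps_r, e$eps_H,
                                          e$d_H, e$T, e$eps_H2O, e$A_DF)
  p <- cfg$protein
  cfg$protein_obj <- protein_spec(p$z_p, p$diameter, p$D_p, p$molar_mass, p$c_bulk)
  a <- cfg$adsorption
  cfg$adsorption_obj <- adsorption_model(a$kind, a$K_ads, a$Gamma_max, a$n0,
                                         cfg$graphene$v_f)
  class(cfg) <- "run_config"
  cfg
}

.config_f_grid <- function(cfg) {
  seq(cfg$grid$f_min, cfg$grid$f_max, length.out = cfg$grid$n_f)
}

#' Load and validate a YAML configuration file
#'
#' Missing keys take their [default_config()] values (an empty file yields
#' the full default scenario); unknown keys are rejected with the offending
#' key path. Quantities may be given as numbers in canonical units or as
#' `"<value> <unit>"` strings (e.g. `c_bulk: "1.18 g/L"`,
#' `d_H: "0.5 nm"`); everything is normalized to SI internally.
#'
#' @param path YAML file path.
#' @return validated `run_config` with all defaults materialized.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(unclass(default_config()), user)
  .materialize_config(cfg)
}

#' Build the absorber layer stack from a configuration
#'
#' Superstrate: electrolyte with permittivity
#' `eps_H2O_optical + A_DF * sqrt(c_salt)` (Debye-Falkenhagen correction on
#' the THz-band water permittivity). Then graphene sheet / dielectric
#' spacer / graphene sheet / PEC.
#'
#' @param config a `run_config`.
#' @param E_f operating Fermi level of both graphene sheets (eV); default
#'   the baseline value from the config.
#' @return a [layer_stack()].
#' @export
build_stack <- function(config = default_config(), E_f = NULL) {
  config <- .materialize_config(config)
  if (is.null(E_f)) E_f <- config$graphene$E_f_baseline
  eps_sol <- electrolyte_permittivity(config$stack$eps_H2O_optical,
                                      config$electrolyte$A_DF,
                                      config$electrolyte$c_salt)
  gp <- graphene_optical_params(E_f = E_f, tau = config$graphene$tau,
                                T = config$graphene$T, v_f = config$graphene$v_f)
  layer_stack(
    n_in = sqrt(eps_sol),
    layers = list(
      sheet_layer(gp, form = config$graphene$interband_form),
      slab_layer(config$stack$spacer_thickness, eps = config$stack$spacer_eps),
      sheet_layer(gp, form = config$graphene$interband_form)
    ),
    backing = config$stack$backing)
}

#' Synthetic Lorentzian resonance spectrum
#'
#' Test fixture for the metrics module: an absorption line
#' `A(f) = A_peak (w/2)^2 / ((f - f_r)^2 + (w/2)^2)` with optional seeded
#' multiplicative Gaussian noise; `R = 1 - A`, `T = 0` (PEC-like
#' bookkeeping).
#'
#' @param f_r line centre (THz), inside the grid.
#' @param FWHM full width at half maximum (THz).
#' @param A_peak peak absorption in (0, 1].
#' @param f_grid frequency grid (THz); default the [default_config()] grid.
#' @param seed integer seed used when `noise > 0`.
#' @param noise relative noise amplitude on `A`.
#' @return a `spectral_response`.
#' @export
make_lorentzian_fixture <- function(f_r, FWHM, A_peak = 0.99,
                                    f_grid = NULL, seed = 1, noise = 0) {
  if (is.null(f_grid)) f_grid <- .config_f_grid(default_config())
  stopifnot(FWHM > 0, A_peak > 0, A_peak <= 1,
            f_r > min(f_grid), f_r < max(f_grid))
  hw <- FWHM / 2
  A <- A_peak * hw^2 / ((f_grid - f_r)^2 + hw^2)
  if (noise > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    A <- A * (1 + noise * stats::rnorm(length(A)))
  }
  structure(list(f_grid = f_grid, R = 1 - A, T_trans = rep(0, length(A)),
                 A = A, r = NULL, t = NULL),
            class = "spectral_response")
}

# Deterministic CSV writer with unit-comment header.
.write_csv_units <- function(df, path, unit_comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", unit_comment), con)
  writeLines(paste(names(df), collapse = ","), con)
  rows <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.12g", col) else as.character(col)
  }), sep = ","))
  writeLines(rows, con)
}

#' Write sweep outputs and a reproducibility manifest
#'
#' Emits one spectrum CSV per concentration (`f_THz,R,T,A`), a metrics JSON
#' (pairwise and reference-based), a summary CSV, and `manifest.json`
#' carrying the config echo, package version, seed, timestamp and an md5
#' checksum per output file. Re-running with the same config and seed
#' reproduces identical checksums (the timestamp is not checksummed).
#'
#' @param result a `sweep_result` (or list of them, one per mode).
#' @param outdir output directory (created if needed).
#' @param seed the seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(result, outdir, seed = NULL) {
  if (inherits(result, "sweep_result")) result <- list(result)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  summary_rows <- list()
  for (res in result) {
    for (i in seq_along(res$concentrations)) {
      df <- as.data.frame(res$spectra[[i]])
      fn <- file.path(outdir, sprintf("spectrum_%s_c%02d.csv", res$mode, i))
      .write_csv_units(df, fn, sprintf(
        "f_THz [THz], R, T, A (dimensionless); mode=%s c=%g g/L",
        res$mode, res$concentrations[i]))
      files <- c(files, fn)
    }
    mfn <- file.path(outdir, sprintf("metrics_%s.json", res$mode))
    jsonlite::write_json(list(mode = res$mode,
                              pairwise = res$metrics_pairwise,
                              vs_reference = res$metrics_vs_ref,
                              sigma_b_THz = res$sigma_b),
                         mfn, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, mfn)
    for (i in seq_along(res$concentrations)) {
      r <- res$records[[i]]
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        mode = res$mode, c_gL = r$c_gL, n_cm2 = m2_to_cm2(r$n),
        Ef_eV = r$gating$E_f, Eg_eV = r$gating$E_g,
        C_EDL_Fm2 = r$caps$C_EDL, C_Q_Fm2 = r$caps$C_Q,
        C_total_Fm2 = r$caps$C_total,
        fr_THz = r$features$f_r, FWHM_THz = r$features$FWHM,
        A_peak = r$features$A_peak)
    }
  }
  sdf <- do.call(rbind, summary_rows)
  sfn <- file.path(outdir, "summary.csv")
  .write_csv_units(sdf, sfn,
    "per-concentration states: n [cm^-2], E [eV], C [F/m^2], f [THz]")
  files <- c(files, sfn)
  checks <- tools::md5sum(files)
  manifest <- list(
    package = "grapheneSPR",
    version = as.character(utils::packageVersion("grapheneSPR")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = .config_echo(result[[1]]$config),
    checksums = as.list(checks))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Plain-list config echo (drop constructed objects).
.config_echo <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$electrolyte_obj <- cfg$protein_obj <- cfg$adsorption_obj <- NULL
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("grapheneSPR run configuration\n")
  utils::str(.config_echo(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
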