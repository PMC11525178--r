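# Schema of recognized config keys per subcommand. Values are defaults
# (NULL = required or optional without default).
.mf_schema <- function() {
  common <- list(seed = NULL, out = NULL, log_level = "info")
  list(
    "simulate-ring" = c(common, list(
      H_um = NULL, D_um = NULL, t_um = NULL, E_kPa = 80, nu = 0.4995,
      mode = "flat_plates", arc_half_angle = 30, penalty = 1e3,
      formulation = "plane_strain", max_narrowing_um = NULL, n_steps = NULL,
      resolution = c(96, 4))),
    "calibrate-alpha" = c(common, list(
      H_um = c(20, 60, 100), D_um = c(140, 180, 220), t_um = c(5, 15, 25),
      E_kPa = c(5, 42.5, 80), nu = 0.4995, mode = "flat_plates",
      formulation = "plane_strain", resolution = c(96, 4), cache_dir = NULL)),
    "fit-afm" = c(common, list(
      curve = NULL, half_angle = 20, nu = 0.5, prefactor = 0.7453,
      spring_constant_N_per_m = 0.2)),
    "fit-uniaxial" = c(common, list(record = NULL, window = c(0, 0.05))),
    "extract" = c(common, list(
      stack = NULL, pixel_size_um = 0.59, time_step_min = 30,
      register_mode = "translation", method = "otsu")),
    "infer-force" = c(common, list(
      trace = NULL, k_nN_per_um = NULL, k_N_per_m = NULL,
      H_um = NULL, D_um = NULL, t_um = NULL, E_kPa = NULL,
      alpha = MF_ALPHA_DEFAULT, impulse_window_min = 60)),
    "cohort" = c(common, list(
      traces = NULL, k_nN_per_um = NULL, times_min = NULL)),
    "synth" = c(common, list(
      what = "trajectory", s_max = 8, tau = 45, mode = "compressive",
      noise_sd = 0, width0_um = 180, k_nN_per_um = NULL, n = 10,
      variability = 0.15, E_kPa = 80, theta = 20, noise = 0,
      pixel_size_um = 0.59, ring_thickness_um = 15))
  )
}

#' Validate and normalize a run configuration
#'
#' Reads a YAML or JSON configuration, checks it against the schema of the
#' named subcommand (unknown keys are an error, listed by name), fills
#' defaults (e.g. `alpha = 7.718`, `nu = 0.5` for AFM fits, a 60-min impulse
#' window) and normalizes units: a stiffness supplied as `k_N_per_m` is
#' converted to nN/um (x 1000).
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`), or a named
#'   list already in memory.
#' @param subcommand one of the pipeline stages; defaults to the config's
#'   own `subcommand` entry.
#' @return A normalized config of class `mf_config`.
#' @export
validate_config <- function(path, subcommand = NULL) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) .err("unreadable-input", "no such file: %s", path)
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  } else if (is.list(path)) path else
    .err("invalid-config", "config must be a file path or a named list")

  if (is.null(subcommand)) subcommand <- cfg$subcommand
  schema <- .mf_schema()
  if (is.null(subcommand) || !subcommand %in% names(schema))
    .err("usage", "unknown or missing subcommand (one of: %s)",
         paste(names(schema), collapse = ", "))
  cfg$subcommand <- NULL
  spec <- schema[[subcommand]]

  unknown <- setdiff(names(cfg), names(spec))
  if (length(unknown))
    .err("invalid-config", "unknown config key(s): %s",
         paste(unknown, collapse = ", "))

  merged <- modifyList(spec, cfg, keep.null = TRUE)
  # unit normalization
  if (subcommand %in% c("infer-force", "cohort") &&
      !is.null(merged$k_N_per_m)) {
    if (!is.null(merged$k_nN_per_um))
      .err("invalid-config", "give k in exactly one unit (k_nN_per_um or k_N_per_m)")
    merged$k_nN_per_um <- n_per_m_to_nn_per_um(merged$k_N_per_m)
    merged$k_N_per_m <- NULL
  }
  merged$subcommand <- subcommand
  structure(merged, class = "mf_config")
}

#' @method print mf_config
#' @export
print.mf_config <- function(x, ...) {
  cat(sprintf("mf_config: %s\n", x$subcommand))
  for (k in setdiff(names(x), "subcommand"))
    if (!is.null(x[[k]]))
      cat(sprintf("  %s: %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}

# md5 of the normalized config, for provenance
.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

.write_provenance <- function(cfg, out_dir, outputs) {
  prov <- list(
    subcommand = cfg$subcommand,
    config_hash = .config_hash(unclass(cfg)),
    package_version = as.character(utils::packageVersion("morphoforce")),
    seed = if (is.null(cfg$seed)) NA else cfg$seed,
    outputs = outputs
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# resolve k for inference configs: direct or via geometry + E + alpha
.resolve_k <- function(cfg) {
  if (!is.null(cfg$k_nN_per_um)) return(cfg$k_nN_per_um)
  if (!is.null(cfg$H_um) && !is.null(cfg$D_um) && !is.null(cfg$t_um) &&
      !is.null(cfg$E_kPa))
    return(predict_stiffness(cylinder_geometry(cfg$H_um, cfg$D_um, cfg$t_um),
                             cfg$E_kPa, alpha = cfg$alpha))
  .err("invalid-config", "supply k_nN_per_um or the full geometry (H_um, D_um, t_um, E_kPa)")
}

#' Run one pipeline stage from a validated configuration
#'
#' Executes the configured subcommand, writes its artifacts (CSV/JSON) plus a
#' `provenance.json` (config hash, package version, seed) into `out_dir`,
#' and returns the paths. Stages are deterministic for a fixed config and
#' seed. Errors propagate as R conditions; the command-line wrapper turns
#' them into a non-zero exit status.
#'
#' @param config an [validate_config()] result (or a list/path accepted by
#'   it).
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `out` entry.
#' @return Invisibly, a named list of written file paths.
#' @export
mf_run <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "mf_config")) config else validate_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out
  if (is.null(out_dir)) .err("usage", "no output directory given")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- cfg$seed

  outputs <- switch(cfg$subcommand,
    "simulate-ring" = {
      geom <- cylinder_geometry(cfg$H_um, cfg$D_um, cfg$t_um)
      mesh <- build_ring_mesh(geom, cfg$resolution)
      sol <- solve_diametral_compression(
        mesh, material_model(cfg$E_kPa, nu = cfg$nu),
        contact = contact_config(cfg$mode, cfg$arc_half_angle, cfg$penalty),
        max_narrowing = cfg$max_narrowing_um, n_steps = cfg$n_steps,
        formulation = cfg$formulation)
      p <- file.path(out_dir, "curve.csv")
      write_fd_curve_csv(sol$curve, p)
      pu <- file.path(out_dir, "displacements.csv")
      write.csv(data.frame(x_um = sol$solution$node_coords[, 1],
                           y_um = sol$solution$node_coords[, 2],
                           ux_um = sol$solution$u[, 1],
                           uy_um = sol$solution$u[, 2]), pu, row.names = FALSE)
      list(curve = p, displacements = pu)
    },
    "calibrate-alpha" = {
      sweep <- run_sweep(cfg$H_um, cfg$D_um, cfg$t_um, cfg$E_kPa,
                         resolution = cfg$resolution,
                         contact = contact_config(cfg$mode),
                         nu = cfg$nu, formulation = cfg$formulation,
                         cache_dir = cfg$cache_dir)
      fit <- fit_alpha(sweep)
      ps <- file.path(out_dir, "sweep.csv")
      write.csv(as.data.frame(sweep), ps, row.names = FALSE)
      pa <- file.path(out_dir, "alpha.json")
      jsonlite::write_json(list(alpha = fit$alpha, r_squared = fit$r_squared,
                                max_rel_residual = fit$max_rel_residual,
                                n_records = nrow(fit$records),
                                alpha_shipped = alpha_default()),
                           pa, auto_unbox = TRUE, digits = NA)
      list(sweep = ps, alpha = pa)
    },
    "fit-afm" = {
      curve <- read_afm_csv(cfg$curve, tip_half_angle = cfg$half_angle,
                            spring_constant = cfg$spring_constant_N_per_m)
      fit <- fit_hertz_pyramidal(curve, nu = cfg$nu, prefactor = cfg$prefactor)
      p <- file.path(out_dir, "hertz_fit.json")
      jsonlite::write_json(list(E_kPa = pa_to_kpa(fit$E_est),
                                contact_point_um = fit$contact_point,
                                rms_residual_nN = fit$rms_residual),
                           p, auto_unbox = TRUE, digits = NA)
      list(fit = p)
    },
    "fit-uniaxial" = {
      rec <- read_stress_strain_csv(cfg$record)
      E <- fit_uniaxial_modulus(rec, window = cfg$window)
      p <- file.path(out_dir, "uniaxial_fit.json")
      jsonlite::write_json(list(E_kPa = pa_to_kpa(E),
                                window = cfg$window), p,
                           auto_unbox = TRUE, digits = NA)
      list(fit = p)
    },
    "extract" = {
      stack <- read_image_stack(cfg$stack, pixel_size = cfg$pixel_size_um,
                                time_step = cfg$time_step_min)
      trace <- extract_trace(stack, mode = cfg$register_mode,
                             method = cfg$method)
      p <- file.path(out_dir, "trace.csv")
      write_trace_csv(trace, p)
      list(trace = p)
    },
    "infer-force" = {
      trace <- read_trace_csv(cfg$trace)
      prof <- force_profile(trace, k = .resolve_k(cfg),
                            impulse_window = cfg$impulse_window_min)
      p <- file.path(out_dir, "profile.csv")
      write_profile_csv(prof, p)
      ps <- file.path(out_dir, "summary.json")
      jsonlite::write_json(list(
        k_nN_per_um = prof$k,
        peak_force_nN = max(abs(prof$force), na.rm = TRUE),
        final_energy_pJ = tail(prof$energy, 1),
        max_impulse_nN_min = prof$max_impulse_60,
        atp_equivalent = atp_equivalent(max(tail(prof$energy, 1), 0))),
        ps, auto_unbox = TRUE, digits = NA)
      list(profile = p, summary = ps)
    },
    "cohort" = {
      files <- sort(list.files(cfg$traces, pattern = "\\.csv$",
                               full.names = TRUE))
      if (!length(files)) .err("unreadable-input", "no trace CSVs in %s", cfg$traces)
      profs <- lapply(files, function(f)
        force_profile(read_trace_csv(f), k = .resolve_k(cfg)))
      summ <- cohort_profile(profs, times = cfg$times_min)
      p <- file.path(out_dir, "summary.csv")
      write.csv(as.data.frame(summ), p, row.names = FALSE)
      list(summary = p)
    },
    "synth" = {
      switch(cfg$what,
        trajectory = {
          tr <- make_trajectory(s_max = cfg$s_max, tau = cfg$tau,
                                mode = cfg$mode, noise_sd = cfg$noise_sd,
                                seed = seed, width0 = cfg$width0_um,
                                k = cfg$k_nN_per_um)
          p <- file.path(out_dir, "trace.csv")
          write_trace_csv(tr$trace, p)
          pt <- file.path(out_dir, "truth.json")
          jsonlite::write_json(tr$truth, pt, auto_unbox = TRUE, digits = NA)
          list(trace = p, truth = pt)
        },
        cohort = {
          co <- make_cohort(n = cfg$n, variability = cfg$variability,
                            seed = seed, s_max = cfg$s_max, tau = cfg$tau,
                            mode = cfg$mode, noise_sd = cfg$noise_sd,
                            width0 = cfg$width0_um, k = cfg$k_nN_per_um)
          paths <- vapply(seq_along(co), function(i) {
            p <- file.path(out_dir, sprintf("trace_%02d.csv", i))
            write_trace_csv(co[[i]]$trace, p)
            p
          }, character(1))
          pt <- file.path(out_dir, "truth.json")
          jsonlite::write_json(lapply(co, `[[`, "truth"), pt, digits = NA)
          list(traces = paths, truth = pt)
        },
        movie = {
          tr <- make_trajectory(s_max = cfg$s_max, tau = cfg$tau,
                                mode = cfg$mode, seed = seed,
                                width0 = cfg$width0_um)
          mv <- render_movie(tr$trace, pixel_size = cfg$pixel_size_um,
                             ring_thickness = cfg$ring_thickness_um,
                             photon_scale = 200, gauss_sd = 0.01, seed = seed)
          p <- file.path(out_dir, "movie.tif")
          write_image_stack(mv$stack, p)
          pt <- file.path(out_dir, "truth.json")
          jsonlite::write_json(mv$truth, pt, digits = NA)
          list(movie = p, truth = pt)
        },
        afm = {
          af <- make_afm_curve(E_kPa = cfg$E_kPa, theta = cfg$theta,
                               noise = cfg$noise, seed = seed)
          p <- file.path(out_dir, "afm.csv")
          write.csv(data.frame(depth_um = af$curve$depth,
                               force_nN = af$curve$force), p, row.names = FALSE)
          pt <- file.path(out_dir, "truth.json")
          jsonlite::write_json(af$truth, pt, auto_unbox = TRUE, digits = NA)
          list(curve = p, truth = pt)
        },
        .err("usage", "unknown synth target '%s'", cfg$what))
    },
    .err("usage", "unknown subcommand '%s'", cfg$subcommand)
  )
  .write_provenance(cfg, out_dir, outputs)
  invisible(c(outputs, provenance = file.path(out_dir, "provenance.json")))
}
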