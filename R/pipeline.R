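#' Default pipeline configuration
#'
#' A single nested list drives \code{\link{run_pipeline}}: the gelation
#' schedule, movie geometry, per-stage analysis parameters, an optional
#' synthetic rheology block, and one global seed from which every stochastic
#' step derives its own sub-seed (\code{\link{derive_seed}}: stage name +
#' global seed).  The defaults use a compact movie geometry (128 px, 200
#' frames, 150 particles) so a full six-movie run stays desk-scale; the
#' physical defaults (50 Hz, 0.1 um/px, 0.57 um probes) match the imaging
#' regime the synthetic module emulates.
#'
#' @param ... name = value overrides merged into the defaults (nested lists
#'   are merged shallowly per top-level name).
#' @return a configuration list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = NULL,
    schedule = default_gelation_schedule(),
    movie = list(n_particles = 150L, n_frames = 200L, image_px = 128L,
                 pixel_size = 0.1, frame_rate = 50, psf_sigma = 0.7,
                 peak_intensity = 300, background = 100,
                 read_noise_sigma = 3, shot_noise = FALSE, bit_depth = 16L),
    piv = list(lag = 0.1, block_size = 32L, search_radius = 8L,
               overlap = 0.5, max_pairs = 10L),
    dva = list(max_pairs = 60L),
    ddm = list(max_pairs = 60L),
    rheology = list(enabled = TRUE, tc = 32,
                    aging_exponent_storage = -0.23,
                    aging_exponent_loss = -0.38,
                    omegas = c(1, 5, 10, 50, 100), noise_cv = 0))
  dots <- list(...)
  for (nm in names(dots)) {
    # plain option lists merge shallowly; classed objects (e.g. a
    # gelation_schedule) replace the default wholesale
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
        !is.object(dots[[nm]]) && !is.object(cfg[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

# Canonical config hash: md5 of the deparsed configuration (the output
# location is not part of the scientific configuration).
.config_hash <- function(cfg) {
  cfg$outdir <- NULL
  cfg$schedule <- unclass(cfg$schedule)
  txt <- paste(deparse(cfg, control = "exact"), collapse = "\n")
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Run the full simulate-analyze-report pipeline
#'
#' For every stage of the gelation schedule: simulate probe trajectories,
#' render a movie, then run PIV (mean displacement), DVA (variance curve,
#' order parameter, stretched-exponential fit, microscopic viscosity) and
#' DDM (structure function, probe-scale ISF, stretched fit, microscopic
#' viscosity, Gaussian-inversion MSD exponent).  Stages whose relaxation
#' does not complete within the movie (arrested states) yield NA analysis
#' entries with the diagnostic recorded, mirroring how late-stage
#' experimental curves must be discarded when long-lag averaging is
#' insufficient.  Globally, the mobility-curve changepoint gives the
#' arrest time, and the synthetic rheology trace (when enabled) gives the
#' Winter-Chambon gel point and aging exponents.
#'
#' Reruns with an identical configuration are bit-identical; the report
#' carries the configuration hash and global seed.
#'
#' @param config a configuration list from
#'   \code{\link{default_pipeline_config}} (or a path to a YAML/JSON file
#'   with the same structure, in which case \code{schedule} may be omitted
#'   to use the default).
#' @param quiet suppress per-stage progress lines?
#' @return an object of class \code{"gelation_report"}: \code{table} (one
#'   row per elapsed time), \code{arrest_time}, \code{gel_point},
#'   \code{aging}, \code{mobility}, \code{config_hash}, \code{seed},
#'   \code{diagnostics}.
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- .load_config(config)
  .validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg <- config
  hash <- .config_hash(cfg)
  sched <- cfg$schedule
  R <- sched$probe_radius; Temp <- sched$temperature
  q_probe <- 2 * pi / R
  mv <- cfg$movie
  optics <- optics_model(pixel_size = mv$pixel_size,
                         image_shape = mv$image_px,
                         psf_sigma = mv$psf_sigma,
                         peak_intensity = mv$peak_intensity,
                         background = mv$background,
                         read_noise_sigma = mv$read_noise_sigma,
                         shot_noise = mv$shot_noise,
                         bit_depth = mv$bit_depth)
  dt <- 1 / mv$frame_rate
  box <- mv$image_px * mv$pixel_size

  n <- length(sched$stages)
  tab <- data.frame(elapsed_min = vapply(sched$stages, `[[`, 0, "elapsed_time"),
                    mobility = NA_real_, dva_tau = NA_real_,
                    dva_beta = NA_real_, eta_dva = NA_real_,
                    ddm_tau = NA_real_, ddm_beta = NA_real_,
                    eta_ddm = NA_real_, msd_exponent = NA_real_)
  diagnostics <- list()
  field_sets <- vector("list", n)

  for (i in seq_len(n)) {
    st <- sched$stages[[i]]
    say("stage t = %g min: simulating (%s) and rendering ...",
        st$elapsed_time, st$motion$kind)
    tr <- simulate_trajectories(st$motion, mv$n_particles, mv$n_frames, dt,
                                box = box,
                                seed = derive_seed(cfg$seed,
                                                   paste0("traj", i)))
    stk <- render_movie(tr, optics,
                        seed = derive_seed(cfg$seed, paste0("render", i)),
                        elapsed_time = st$elapsed_time)
    field_sets[[i]] <- displacement_field(
      stk, lag = cfg$piv$lag, block_size = cfg$piv$block_size,
      search_radius = cfg$piv$search_radius, overlap = cfg$piv$overlap,
      max_pairs = cfg$piv$max_pairs)

    dva_res <- tryCatch({
      dc <- differential_variance_curve(stk, max_pairs = cfg$dva$max_pairs)
      dc <- order_parameter(dc)
      fit <- fit_stretched_exponential(dc$lags, dc$q_values)
      list(fit = fit, eta = microscopic_viscosity(fit, R, Temp, "dva")$eta)
    }, error = function(e) e)
    if (inherits(dva_res, "error")) {
      diagnostics[[paste0("dva_t", st$elapsed_time)]] <-
        conditionMessage(dva_res)
    } else {
      tab$dva_tau[i] <- dva_res$fit$tau
      tab$dva_beta[i] <- dva_res$fit$beta
      tab$eta_dva[i] <- dva_res$eta
    }

    ddm_res <- tryCatch({
      sf <- structure_function(stk, max_pairs = cfg$ddm$max_pairs)
      sf <- estimate_noise_and_amplitude(sf)
      isf <- extract_isf(sf, q_probe)
      fit <- fit_stretched_exponential(isf$lags, isf$f_values)
      msd <- isf_to_msd(isf)
      list(fit = fit, msd = msd,
           eta = microscopic_viscosity(fit, R, Temp, "ddm")$eta)
    }, error = function(e) e)
    if (inherits(ddm_res, "error")) {
      diagnostics[[paste0("ddm_t", st$elapsed_time)]] <-
        conditionMessage(ddm_res)
    } else {
      tab$ddm_tau[i] <- ddm_res$fit$tau
      tab$ddm_beta[i] <- ddm_res$fit$beta
      tab$eta_ddm[i] <- ddm_res$eta
      tab$msd_exponent[i] <- ddm_res$msd$exponent
    }
  }

  mob <- mobility_curve(field_sets)
  tab$mobility <- mob$values
  arrest <- tryCatch(detect_changepoint(mob), error = function(e) e)
  arrest_time <- if (inherits(arrest, "error")) NA_real_ else
    if (arrest$degenerate) NA_real_ else arrest$changepoint

  gel_point <- NULL; aging <- NULL; rheo <- NULL
  if (isTRUE(cfg$rheology$enabled)) {
    rp <- cfg$rheology
    rheo <- synthesize_rheology(
      tc = rp$tc, aging_exponent_storage = rp$aging_exponent_storage,
      aging_exponent_loss = rp$aging_exponent_loss, omegas = rp$omegas,
      noise_cv = rp$noise_cv, seed = derive_seed(cfg$seed, "rheology"))
    rheo <- loss_tangent(rheo)
    gel_point <- detect_gel_point_winter(rheo)
    aging <- aging_power_laws(rheo)
  }

  report <- structure(list(table = tab, mobility = mob,
                           arrest_time = arrest_time,
                           arrest_fit = if (inherits(arrest, "error")) NULL
                                        else arrest,
                           gel_point = gel_point, aging = aging,
                           rheology = rheo,
                           config_hash = hash, seed = cfg$seed,
                           diagnostics = diagnostics),
                      class = "gelation_report")
  if (!is.null(cfg$outdir)) .write_report_artifacts(report, cfg$outdir)
  report
}

.load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$schedule)) raw$schedule <- default_gelation_schedule()
  do.call(default_pipeline_config, raw)
}

.validate_config <- function(cfg) {
  .assert(is.list(cfg), "config must be a list")
  need <- c("seed", "schedule", "movie", "piv", "dva", "ddm")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop(sprintf("config error: missing block(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  .assert(inherits(cfg$schedule, "gelation_schedule"),
          "config error: 'schedule' must be a gelation_schedule")
  mv_need <- c("n_particles", "n_frames", "image_px", "pixel_size",
               "frame_rate", "psf_sigma")
  missing <- setdiff(mv_need, names(cfg$movie))
  if (length(missing))
    stop(sprintf("config error: movie block missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.write_report_artifacts <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$table, file.path(outdir, "report_table.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(report$mobility),
            file.path(outdir, "mobility_curve.csv"), row.names = FALSE)
  if (!is.null(report$rheology))
    write_rheology(report$rheology, file.path(outdir, "rheology.csv"))
  summary <- list(
    arrest_time_min = report$arrest_time,
    gel_point_min = if (!is.null(report$gel_point)) report$gel_point$tc,
    tan_delta_at_tc = if (!is.null(report$gel_point))
      report$gel_point$tan_delta_at_tc,
    aging_exponents = if (!is.null(report$aging))
      list(storage = report$aging$storage$exponent,
           loss = report$aging$loss$exponent,
           tan_delta = report$aging$tan_delta$exponent),
    config_hash = report$config_hash, seed = report$seed,
    diagnostics = report$diagnostics)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(outdir, "report.json"))
  invisible(outdir)
}

#' Hash of a gelation report's numerical content
#'
#' Used to assert end-to-end determinism: identical configuration and seed
#' must yield an identical hash.
#'
#' @param report a \code{"gelation_report"}.
#' @return md5 string.
#' @export
report_hash <- function(report) {
  f <- tempfile()
  num <- list(table = report$table, arrest = report$arrest_time,
              tc = if (!is.null(report$gel_point)) report$gel_point$tc,
              mobility = report$mobility$values)
  writeLines(jsonlite::toJSON(num, digits = NA, na = "string"), f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' @export
print.gelation_report <- function(x, ...) {
  cat("<gelation_report> seed", x$seed, "config", substr(x$config_hash, 1, 8),
      "\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("arrest time (PIV changepoint): %s min\n",
              format(signif(x$arrest_time, 4))))
  if (!is.null(x$gel_point))
    cat(sprintf("Winter-Chambon gel point: %.4g min (tan delta = %.4g)\n",
                x$gel_point$tc, x$gel_point$tan_delta_at_tc))
  if (!is.null(x$aging))
    cat(sprintf("aging exponents: G' %.3f, G'' %.3f, tan(delta) %.3f\n",
                x$aging$storage$exponent, x$aging$loss$exponent,
                x$aging$tan_delta$exponent))
  if (length(x$diagnostics)) {
    cat("diagnostics:\n")
    for (nm in names(x$diagnostics))
      cat("  -", nm, ":", substr(x$diagnostics[[nm]], 1, 100), "\n")
  }
  invisible(x)
}
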