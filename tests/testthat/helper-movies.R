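# Shared synthetic fixtures, built once per session and cached by key.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Standard Brownian movie at a milk-like viscosity (eta in mPa s).
brownian_movie <- function(eta = 2, seed = 101, n_particles = 300,
                           n_frames = 500) {
  key <- sprintf("bm_%g_%d_%d_%d", eta, seed, n_particles, n_frames)
  fixture(key, function() {
    D <- stokes_einstein_d(eta, 0.57)
    tr <- simulate_trajectories(
      motion_model("brownian", diffusion_coefficient = D),
      n_particles, n_frames, 0.02, box = 25.6, seed = seed)
    list(traj = tr, D = D,
         stack = render_movie(tr, optics_model(), seed = seed + 1L))
  })
}

# Structure function with A/B estimated, cached alongside the movie.
movie_sf <- function(mv, key, max_pairs = 60) {
  fixture(paste0("sf_", key), function()
    estimate_noise_and_amplitude(
      structure_function(mv$stack, max_pairs = max_pairs)))
}

loglog_slope <- function(x, y) unname(coef(lm(log(y) ~ log(x)))[2])

# Compact paired configuration: movie schedule and rheology sharing one
# arrest/gelation epoch, at a geometry small enough for a fast end-to-end
# run (arrest programmed at the 40 min stage; rheology tc = 32 min).
paired_config <- function(seed = 3) {
  # mild pre-gel thickening (as in slowly acidifying milk), then arrest
  pre <- lapply(0:3, function(i)
    list(elapsed_time = i * 10,
         motion = motion_model("brownian", diffusion_coefficient = 1),
         viscosity = c(2.0, 2.1, 2.25, 2.4)[i + 1]))
  # progressive arrest: partial caging at 40 min (MSD plateau (0.1 um)^2),
  # deep caging at 50 min -- a gradual collapse like the experimental one
  frozen <- list(
    list(elapsed_time = 40,
         motion = motion_model("trapped", trap_stiffness = 20,
                               noise_scale = 0.05)),
    list(elapsed_time = 50,
         motion = motion_model("trapped", trap_stiffness = 20,
                               noise_scale = 0.002)))
  default_pipeline_config(
    seed = seed,
    schedule = gelation_schedule(c(pre, frozen)),
    movie = list(n_particles = 150L, n_frames = 150L, image_px = 96L),
    piv = list(max_pairs = 25L),
    dva = list(max_pairs = 40L),
    ddm = list(max_pairs = 40L))
}

# Cached end-to-end run; artifacts land in a session-stable temp directory
# recorded as attr(report, "outdir").
paired_report <- function(seed = 3) {
  fixture(sprintf("paired_%d", seed), function() {
    cfg <- paired_config(seed)
    cfg$outdir <- file.path(tempdir(), sprintf("gelrun_%d", seed))
    rep <- suppressMessages(run_pipeline(cfg, quiet = TRUE))
    attr(rep, "outdir") <- cfg$outdir
    rep
  })
}

# A tiny textured two-frame stack for PIV tests (static particles).
texture_pair <- function(seed = 5, n = 150, px = 128) {
  fixture(sprintf("tex_%d_%d_%d", seed, n, px), function() {
    tr <- simulate_trajectories(
      motion_model("brownian", diffusion_coefficient = 0),
      n, 2, 0.02, box = px * 0.1, seed = seed)
    render_movie(tr, optics_model(image_shape = px, psf_sigma = 1.5,
                                  read_noise_sigma = 0), seed = 1)
  })
}
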