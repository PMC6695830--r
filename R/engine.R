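#' Langevin engine configuration
#'
#' Defaults follow the production MD protocol the supervision loop was
#' designed around: a 2 fs timestep, a Langevin thermostat at 310 K with a
#' low 1 ps^-1 friction, and frames saved every 20 ps.
#'
#' @param dt integration timestep, ps (default 0.002 = 2 fs).
#' @param temperature thermostat temperature, K.
#' @param friction Langevin friction, ps^-1 (0 disables the thermostat).
#' @param frame_stride frame-saving interval, ps; must be an integer
#'   multiple of `dt`.
#' @param seed integer seed used when a segment is started without an
#'   inherited RNG state.
#' @return An `engine_config` list.
#' @export
engine_config <- function(dt = 0.002, temperature = 310, friction = 1.0,
                          frame_stride = 20, seed = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (temperature < 0) stop("temperature must be non-negative")
  if (friction < 0) stop("friction must be non-negative")
  steps <- frame_stride / dt
  if (abs(steps - round(steps)) > 1e-8)
    stop("frame_stride must be an integer multiple of dt")
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 frame_stride = frame_stride, seed = as.integer(seed)),
            class = "engine_config")
}

#' Maxwell-Boltzmann velocity sampling
#'
#' Draws each velocity component from a zero-mean normal with variance
#' kB*T/m (in A^2/ps^2), the Maxwell-Boltzmann marginal used to (re)assign
#' atomic velocities on supervision restarts.
#'
#' @param masses atomic masses, amu.
#' @param temperature temperature, K.
#' @param seed optional integer seed; when given, the draw uses a private
#'   RNG stream and leaves the caller's stream untouched. When `NULL` the
#'   current stream is consumed.
#' @return n x 3 matrix of velocities, A/ps.
#' @export
sample_velocities <- function(masses, temperature, seed = NULL) {
  if (any(masses <= 0)) stop("masses must be positive")
  if (temperature < 0) stop("temperature must be non-negative")
  n <- length(masses)
  draw <- function() {
    sd <- sqrt(sumd_constants$kB * temperature * sumd_constants$akma / masses)
    matrix(rnorm(3 * n, 0, rep(sd, 3)), n, 3)
  }
  if (temperature == 0) return(matrix(0, n, 3))
  if (is.null(seed)) draw() else with_private_seed(seed, draw())
}

#' Initial simulation state
#'
#' @param system a `toy_system`.
#' @param temperature temperature for the initial velocity draw, K; 0 gives
#'   zero velocities.
#' @param seed optional seed for the velocity draw.
#' @return A `sim_state`: list with `time` (ps), `positions`, `velocities`
#'   and `rng_state` (NULL until a segment has run).
#' @export
sim_state <- function(system, temperature = 0, seed = NULL) {
  pos <- atom_xyz(system$ligand)
  vel <- sample_velocities(system$ligand$mass, temperature, seed)
  structure(list(time = 0, positions = pos, velocities = vel,
                 rng_state = NULL), class = "sim_state")
}

restore_rng <- function(rng_state, seed) {
  if (is.null(rng_state)) set.seed(seed)
  else assign(".Random.seed", rng_state, envir = globalenv())
}

capture_rng <- function() get(".Random.seed", envir = globalenv())

#' Run one unbiased Langevin segment
#'
#' Integrates NVT Langevin dynamics (BAOAB splitting) of the mobile ligand
#' atoms on the system's toy potential, with reflecting walls at the box
#' boundary. The segment continues the RNG stream stored in `state`
#' (bitwise-reproducible restarts); a fresh state starts the stream from
#' `config$seed`.
#'
#' @param state a [sim_state()].
#' @param system a `toy_system`.
#' @param config an [engine_config()].
#' @param duration segment length, ps; must be a positive integer multiple
#'   of `config$frame_stride`.
#' @param window_index integer provenance tag carried on the segment.
#' @return A `trajectory_segment`: `frames` (natoms x 3 x nframes array),
#'   `times` (ps, excluding the start state), `start_state`, `end_state`,
#'   `window_index`.
#' @export
run_segment <- function(state, system, config, duration, window_index = 0L) {
  nf <- duration / config$frame_stride
  if (duration <= 0 || abs(nf - round(nf)) > 1e-8)
    stop("duration must be a positive integer multiple of frame_stride")
  nsteps <- as.integer(round(duration / config$dt))
  frame_every <- as.integer(round(config$frame_stride / config$dt))

  restore_rng(state$rng_state, config$seed)
  res <- cpp_baoab(state$positions, state$velocities, system$ligand$mass,
                   system$ligand$charge, pot_cpp(system$potential),
                   config$dt, nsteps, config$friction, config$temperature,
                   frame_every, system$box / 2)
  rng <- capture_rng()

  nframes <- res$nframes
  frames <- array(res$frames, dim = c(nrow(state$positions), 3, nframes))
  end_state <- structure(list(time = state$time + duration,
                              positions = res$pos, velocities = res$vel,
                              rng_state = rng), class = "sim_state")
  structure(list(frames = frames,
                 times = state$time + config$frame_stride * seq_len(nframes),
                 start_state = state, end_state = end_state,
                 window_index = as.integer(window_index)),
            class = "trajectory_segment")
}
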