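#' Supervision (SuMD) configuration
#'
#' Parameters of the tabu-like supervision loop: dynamics is run in short
#' windows, the ligand--site distance sampled at regular intervals within
#' each window is fitted to a line, windows with negative slope (ligand
#' approaching) are kept, others are discarded and restarted with freshly
#' randomized velocities, and once the distance drops below `threshold` the
#' supervision is disabled and plain MD continues.
#'
#' @param window_length supervision window, ps. 200 ps suits fast-diffusing
#'   ions; 600 ps is the classic choice for small organic molecules (use
#'   `preset`).
#' @param preset `"ion"` (200 ps) or `"small_molecule"` (600 ps); overridden
#'   by an explicit `window_length`.
#' @param distance_sample_interval spacing of distance samples, ps; default
#'   `window_length / 10`.
#' @param threshold supervision hand-off distance, A (default 5).
#' @param max_consecutive_failures stop after this many rejected windows in
#'   a row (safeguard; default 40).
#' @param max_total_windows hard cap on attempted windows (default 500).
#' @param post_supervision_duration plain-MD tail after binding, ps.
#' @param site_residues residue ids defining the supervised site center;
#'   default: the system's `orthosteric` site.
#' @param ligand_selection optional ligand atom names or indices; default:
#'   all ligand atoms.
#' @return A `supervision_config` list.
#' @export
supervision_config <- function(window_length = NULL,
                               preset = c("ion", "small_molecule"),
                               distance_sample_interval = NULL,
                               threshold = 5,
                               max_consecutive_failures = 40,
                               max_total_windows = 500,
                               post_supervision_duration = 200,
                               site_residues = NULL,
                               ligand_selection = NULL) {
  preset <- match.arg(preset)
  if (is.null(window_length))
    window_length <- switch(preset, ion = 200, small_molecule = 600)
  if (is.null(distance_sample_interval))
    distance_sample_interval <- window_length / 10
  if (threshold <= 0) stop("threshold must be positive")
  if (window_length < 2 * distance_sample_interval)
    stop("window_length must cover at least two distance samples")
  k <- window_length / distance_sample_interval
  if (abs(k - round(k)) > 1e-8)
    stop("window_length must be an integer multiple of distance_sample_interval")
  if (max_consecutive_failures < 1 || max_total_windows < 1)
    stop("failure and window caps must be positive")
  structure(list(window_length = window_length,
                 distance_sample_interval = distance_sample_interval,
                 threshold = threshold,
                 max_consecutive_failures = as.integer(max_consecutive_failures),
                 max_total_windows = as.integer(max_total_windows),
                 post_supervision_duration = post_supervision_duration,
                 site_residues = site_residues,
                 ligand_selection = ligand_selection),
            class = "supervision_config")
}

#' Mass-weighted center of a residue selection
#'
#' @param x a `toy_system` or an atom table ([atom_records()]).
#' @param residue_ids residue ids whose atoms define the site.
#' @return 3-vector, A.
#' @export
site_center <- function(x, residue_ids) {
  atoms <- if (inherits(x, "toy_system")) x$receptor else x
  miss <- setdiff(residue_ids, atoms$resid)
  if (length(miss))
    stop("residue id(s) not present: ", paste(miss, collapse = ", "))
  sel <- atoms[atoms$resid %in% residue_ids, , drop = FALSE]
  colSums(atom_xyz(sel) * sel$mass) / sum(sel$mass)
}

#' Ligand center-of-mass distance to a site center
#'
#' @param positions n x 3 matrix of ligand-atom coordinates (or a 3-vector).
#' @param masses ligand atomic masses, amu.
#' @param center site center 3-vector, A.
#' @return Euclidean distance, A.
#' @export
ligand_distance <- function(positions, masses, center) {
  pos <- as_position_matrix(positions)
  if (nrow(pos) == 0) stop("empty ligand selection")
  masses <- rep_len(masses, nrow(pos))
  com <- colSums(pos * masses) / sum(masses)
  sqrt(sum((com - center)^2))
}

#' Distance series within one supervision window
#'
#' @param time sample times, ps (strictly increasing, equally spaced).
#' @param distance ligand--site distances, A.
#' @return A `distance_series` data.frame.
#' @export
distance_series <- function(time, distance) {
  if (length(time) < 2) stop("a distance series needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("sample times must be strictly increasing")
  if (diff(range(dt)) > 1e-8 * max(dt)) stop("sample times must be equally spaced")
  structure(data.frame(time = time, distance = distance),
            class = c("distance_series", "data.frame"))
}

#' Least-squares slope of a distance series
#'
#' Ordinary least-squares slope of distance on time (A/ps), the quantity the
#' supervision accept/reject rule is based on.
#'
#' @param series a [distance_series()] or data.frame with `time`, `distance`.
#' @return Slope, A/ps.
#' @export
fit_slope <- function(series) {
  if (nrow(series) < 2) stop("a distance series needs at least 2 samples")
  vt <- stats::var(series$time)
  if (vt == 0) stop("zero time variance in distance series")
  # cov/var form: exact zero for a constant series, unlike a QR-based fit
  stats::cov(series$time, series$distance) / vt
}

#' Classify a supervision window
#'
#' `bound` if the final sample is below the threshold (regardless of slope:
#' the stop rule is on distance); otherwise `accept` iff the fitted slope is
#' strictly negative (a slope of exactly zero makes no progress and is
#' rejected); otherwise `reject`.
#'
#' @param series a [distance_series()].
#' @param config a [supervision_config()] (only `threshold` is used).
#' @return One of `"bound"`, `"accept"`, `"reject"`.
#' @export
classify_window <- function(series, config) {
  if (series$distance[nrow(series)] < config$threshold) return("bound")
  if (fit_slope(series) < 0) "accept" else "reject"
}

resolve_ligand_rows <- function(system, selection) {
  lig <- system$ligand
  if (is.null(selection)) return(seq_len(nrow(lig)))
  rows <- if (is.character(selection)) which(lig$name %in% selection)
          else as.integer(selection)
  if (length(rows) == 0 || any(rows < 1) || any(rows > nrow(lig)))
    stop("empty or invalid ligand selection")
  rows
}

#' Run a supervised molecular dynamics (SuMD) simulation
#'
#' Drives the Langevin engine in windows of `sup_config$window_length` ps.
#' After each window, the ligand--site distance sampled every
#' `distance_sample_interval` ps is fitted to a line: negative-slope windows
#' are kept, others are rewound (positions and clock restored to the window
#' start) and restarted with freshly drawn Maxwell-Boltzmann velocities.
#' When a window ends below `threshold` A the supervision is disabled and a
#' plain-MD tail of `post_supervision_duration` ps is appended. The run is
#' fully reproducible for a fixed `seed`.
#'
#' @param system a `toy_system` (see [build_receptor_model()]).
#' @param engine_cfg an [engine_config()].
#' @param sup_cfg a [supervision_config()].
#' @param seed integer master seed (dynamics stream and restart draws derive
#'   from it via separate sub-streams).
#' @return A `sumd_result`: `trajectory` (accepted windows + tail),
#'   `window_log` (one row per attempted window), `termination` (`bound`,
#'   `failure_cap` or `window_cap`), `supervised_time`,
#'   `total_attempted_time`, `first_binding_time` (ps or NA), and the site
#'   `center` used.
#' @export
run_sumd <- function(system, engine_cfg = engine_config(),
                     sup_cfg = supervision_config(), seed = 1) {
  site_res <- sup_cfg$site_residues %||% system$sites$orthosteric
  center <- site_center(system, site_res)
  lig_rows <- resolve_ligand_rows(system, sup_cfg$ligand_selection)
  masses <- system$ligand$mass

  win_cfg <- engine_config(dt = engine_cfg$dt,
                           temperature = engine_cfg$temperature,
                           friction = engine_cfg$friction,
                           frame_stride = sup_cfg$distance_sample_interval,
                           seed = seed)

  # a ligand already below the threshold simply classifies window 1 as
  # bound, degenerating to plain MD
  set.seed(seed)
  state <- sim_state(system)
  state$velocities <- sample_velocities(masses, engine_cfg$temperature)
  state$rng_state <- capture_rng()

  frames <- list(); times <- numeric(0); win_of_frame <- integer(0)
  log_rows <- list()
  n_acc <- 0L; n_rej <- 0L; consec <- 0L
  termination <- "window_cap"; first_bind <- NA_real_
  window <- 0L

  while (window < sup_cfg$max_total_windows) {
    window <- window + 1L
    snapshot <- state
    seg <- tryCatch(
      run_segment(state, system, win_cfg, sup_cfg$window_length, window),
      error = function(e) stop("window ", window, ": ", conditionMessage(e)))
    dists <- apply(seg$frames[lig_rows, , , drop = FALSE], 3, function(p)
      ligand_distance(matrix(p, ncol = 3), masses[lig_rows], center))
    series <- distance_series(seg$times, dists)
    decision <- classify_window(series, sup_cfg)
    slope <- tryCatch(fit_slope(series), error = function(e) NA_real_)
    restart_seed <- NA_integer_

    if (decision == "reject") {
      n_rej <- n_rej + 1L; consec <- consec + 1L
      restart_seed <- as.integer((seed + 104729 * (n_rej %% 20011)) %% 2147483647L)
      state <- snapshot
      state$velocities <- sample_velocities(masses, engine_cfg$temperature,
                                            seed = restart_seed)
      # dynamics noise stream continues past the discarded window
      state$rng_state <- seg$end_state$rng_state
    } else {
      n_acc <- n_acc + 1L; consec <- 0L
      state <- seg$end_state
      nf <- dim(seg$frames)[3]
      frames <- c(frames, lapply(seq_len(nf), function(k) seg$frames[, , k, drop = FALSE]))
      times <- c(times, seg$times)
      win_of_frame <- c(win_of_frame, rep(window, nf))
      if (is.na(first_bind)) {
        below <- which(dists < sup_cfg$threshold)
        if (length(below)) first_bind <- seg$times[below[1]]
      }
    }
    log_rows[[window]] <- data.frame(index = window, slope = slope,
                                     accepted = decision != "reject",
                                     decision = decision,
                                     final_distance = dists[length(dists)],
                                     restart_seed = restart_seed)
    if (decision == "bound") { termination <- "bound"; break }
    if (consec >= sup_cfg$max_consecutive_failures) {
      termination <- "failure_cap"; break
    }
  }

  if (termination == "bound" && sup_cfg$post_supervision_duration > 0) {
    tail_cfg <- engine_config(dt = engine_cfg$dt,
                              temperature = engine_cfg$temperature,
                              friction = engine_cfg$friction,
                              frame_stride = engine_cfg$frame_stride,
                              seed = seed)
    seg <- run_segment(state, system, tail_cfg,
                       sup_cfg$post_supervision_duration, NA_integer_)
    nf <- dim(seg$frames)[3]
    frames <- c(frames, lapply(seq_len(nf), function(k) seg$frames[, , k, drop = FALSE]))
    times <- c(times, seg$times)
    win_of_frame <- c(win_of_frame, rep(NA_integer_, nf))
    state <- seg$end_state
  }

  traj <- build_trajectory(system, frames, times, win_of_frame,
                           stride = sup_cfg$distance_sample_interval)
  structure(list(trajectory = traj,
                 window_log = do.call(rbind, log_rows),
                 termination = termination,
                 supervised_time = n_acc * sup_cfg$window_length,
                 total_attempted_time = (n_acc + n_rej) * sup_cfg$window_length,
                 first_binding_time = first_bind,
                 center = center, threshold = sup_cfg$threshold,
                 seed = as.integer(seed), final_state = state),
            class = "sumd_result")
}

#' @export
print.sumd_result <- function(x, ...) {
  cat("SuMD run (seed ", x$seed, "): ", x$termination, "\n", sep = "")
  cat("  windows: ", nrow(x$window_log), " attempted, ",
      sum(x$window_log$accepted), " accepted\n", sep = "")
  cat("  supervised time: ", x$supervised_time, " ps of ",
      x$total_attempted_time, " ps attempted\n", sep = "")
  if (!is.na(x$first_binding_time))
    cat("  first below threshold at ", x$first_binding_time, " ps\n", sep = "")
  invisible(x)
}

# Assemble a full-system trajectory (frozen receptor + mobile ligand).
build_trajectory <- function(system, lig_frames, times, window, stride) {
  topo <- rbind(system$receptor, system$ligand)
  class(topo) <- c("sumd_atoms", "data.frame")
  natoms <- nrow(topo)
  nf <- length(lig_frames)
  coords <- array(NA_real_, c(natoms, 3, max(nf, 0)))
  rec_xyz <- atom_xyz(system$receptor)
  for (k in seq_len(nf)) {
    coords[seq_len(nrow(rec_xyz)), , k] <- rec_xyz
    coords[nrow(rec_xyz) + seq_len(nrow(system$ligand)), , k] <-
      lig_frames[[k]]
  }
  trajectory(topo, coords, times, stride = stride, window = window)
}
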