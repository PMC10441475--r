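#' Toy dynamics state
#'
#' A snapshot of the toy system: position, optional velocity (underdamped
#' mode only), simulation time, and an opaque RNG token. The token is the
#' generator state at the moment the snapshot was taken, so restarting from
#' a returned state reproduces an uninterrupted run bit for bit.
#'
#' @param position Numeric position vector.
#' @param velocity Numeric velocity vector, or NULL in overdamped mode.
#' @param time Simulation time of the snapshot.
#' @param rng_state Opaque RNG token (a saved `.Random.seed`), or NULL.
#' @return A `toy_state`.
#' @export
toy_state <- function(position, velocity = NULL, time = 0, rng_state = NULL) {
  stopifnot(all(is.finite(position)))
  if (!is.null(velocity)) stopifnot(all(is.finite(velocity)),
                                    length(velocity) == length(position))
  structure(list(position = as.numeric(position),
                 velocity = if (is.null(velocity)) NULL else as.numeric(velocity),
                 time = time, rng_state = rng_state),
            class = "toy_state")
}

#' Integrator configuration
#'
#' Overdamped Euler-Maruyama is the default scheme; `mode = "langevin"`
#' selects an underdamped BAOAB-style integrator (unit mass) that carries
#' velocities, which matters when a supervision restart must preserve both
#' coordinates and velocities. Units: kT = 1, lengths dimensionless,
#' diffusion coefficient D = temperature / friction.
#'
#' @param mode "overdamped" or "langevin".
#' @param timestep Integration timestep (toy time), default 1e-3.
#' @param friction Friction coefficient (1/time), default 1.
#' @param temperature Temperature in kT, default 1. Zero is allowed for
#'   deterministic-descent checks.
#' @param stride Steps between stored frames, default 10.
#' @param seed Optional integer seed applied when a run starts from a state
#'   without an RNG token.
#' @return An `integrator_config`.
#' @export
integrator_config <- function(mode = c("overdamped", "langevin"),
                              timestep = 1e-3, friction = 1,
                              temperature = 1, stride = 10L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(timestep > 0, friction > 0, temperature >= 0, stride >= 1)
  structure(list(mode = mode, timestep = timestep, friction = friction,
                 temperature = temperature, stride = as.integer(stride),
                 seed = seed),
            class = "integrator_config")
}

get_rng_token <- function() {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  get(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rng_token <- function(token) {
  assign(".Random.seed", token, envir = globalenv())
}

new_trajectory <- function(times, coords, stride, timestep,
                           provenance = list(), segments = NULL) {
  coords <- as.matrix(coords)
  if (is.null(segments)) segments <- rep(1L, length(times))
  structure(list(times = times, coords = coords, stride = stride,
                 timestep = timestep, provenance = provenance,
                 segments = segments),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$coords), "frames,", ncol(x$coords),
      "dims, t in [", if (length(x$times)) min(x$times) else NA, ",",
      if (length(x$times)) max(x$times) else NA, "]\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$coords)

#' Concatenate trajectories
#'
#' Frames are concatenated in order; each input becomes its own segment.
#' @param ... `trajectory` objects with matching dimensionality.
#' @return A single `trajectory`.
#' @export
bind_trajectories <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "trajectory")) parts <- parts[[1]]
  parts <- Filter(function(p) n_frames(p) > 0, parts)
  if (!length(parts)) stop("no non-empty trajectories to bind")
  segs <- unlist(lapply(seq_along(parts),
                        function(i) rep(i, n_frames(parts[[i]]))))
  new_trajectory(times = unlist(lapply(parts, `[[`, "times")),
                 coords = do.call(rbind, lapply(parts, `[[`, "coords")),
                 stride = parts[[1]]$stride, timestep = parts[[1]]$timestep,
                 provenance = parts[[1]]$provenance, segments = segs)
}

#' Advance the toy dynamics
#'
#' Integrates `n_steps` steps of the configured scheme from `state` on
#' `field`, storing a frame every `config$stride` steps. The returned state
#' carries the RNG token, so `advance(advance(s, N), N)` is bit-identical to
#' `advance(s, 2N)`.
#'
#' @param state A `toy_state`.
#' @param field A `potential_field`.
#' @param config An `integrator_config`.
#' @param n_steps Number of integration steps (>= 1).
#' @return `list(state = toy_state, trajectory = trajectory)`.
#' @export
advance <- function(state, field, config, n_steps) {
  stopifnot(inherits(state, "toy_state"), inherits(field, "potential_field"),
            inherits(config, "integrator_config"), n_steps >= 1)
  if (length(state$position) != field$dimension)
    stop("state dimension does not match field")
  if (any(abs(state$position) > field$box_half_width))
    stop("state lies outside the field's box")
  if (!is.null(state$rng_state)) {
    set_rng_token(state$rng_state)
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  underdamped <- config$mode == "langevin"
  vel <- state$velocity
  if (underdamped && is.null(vel)) {
    # Maxwell-Boltzmann draw at the configured temperature (unit mass)
    vel <- stats::rnorm(length(state$position),
                        sd = sqrt(config$temperature))
  }
  res <- advance_cpp(state$position,
                     if (underdamped) vel else numeric(0),
                     field$descriptor,
                     config$timestep, config$friction, config$temperature,
                     if (underdamped) 1L else 0L,
                     as.integer(n_steps), config$stride, state$time)
  traj <- new_trajectory(times = res$frame_times, coords = res$frames,
                         stride = config$stride, timestep = config$timestep,
                         provenance = list(field = field$kind,
                                           config = unclass(config)))
  new_state <- toy_state(position = res$final_position,
                         velocity = if (underdamped) res$final_velocity else NULL,
                         time = res$final_time,
                         rng_state = get_rng_token())
  list(state = new_state, trajectory = traj)
}

#' Mean squared displacement of free particles
#'
#' Simulates `n_particles` independent overdamped particles on a flat
#' unbounded potential for time `t` and returns the ensemble MSD with its
#' standard error. Validates the backend against the Einstein relation
#' `MSD = 2 d D t` with `D = temperature / friction`.
#'
#' @param config An `integrator_config` (overdamped).
#' @param n_particles Ensemble size.
#' @param t Elapsed toy time.
#' @param dimension Spatial dimension, default 1.
#' @return List with `msd`, `se`, `expected`, `n`, `t`.
#' @export
msd_free <- function(config, n_particles, t, dimension = 1) {
  stopifnot(inherits(config, "integrator_config"),
            config$mode == "overdamped", n_particles >= 1, t >= 0)
  if (t == 0)
    return(list(msd = 0, se = 0,
                expected = 0, n = n_particles, t = 0))
  n_steps <- max(1L, as.integer(round(t / config$timestep)))
  if (!is.null(config$seed)) set.seed(config$seed)
  r2 <- free_sq_disp_cpp(as.integer(n_particles), as.integer(dimension),
                         n_steps, config$timestep, config$friction,
                         config$temperature)
  D <- config$temperature / config$friction
  list(msd = mean(r2), se = stats::sd(r2) / sqrt(n_particles),
       expected = 2 * dimension * D * n_steps * config$timestep,
       n = n_particles, t = n_steps * config$timestep)
}
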