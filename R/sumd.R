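#' Supervision metric
#'
#' The scalar the supervision algorithm watches. For the toy backend the
#' ligand is a single diffusing particle and the pocket is a set of fixed
#' anchor points in the landscape:
#' * `com_distance` — distance from the particle to the (mass-weighted)
#'   centroid of the anchors;
#' * `pair_distance_set` — distances from the particle to each anchor,
#'   combined by `combine` (mean by default, mirroring a two-atom-pair
#'   gating stage).
#'
#' @param kind "com_distance" or "pair_distance_set".
#' @param anchors Matrix of anchor coordinates (one row per anchor), or a
#'   single coordinate vector.
#' @param combine For pair sets: "single", "mean" or "max".
#' @param masses Optional positive anchor masses (com_distance only).
#' @return A `supervision_metric`.
#' @export
supervision_metric <- function(kind = c("com_distance", "pair_distance_set"),
                               anchors, combine = c("mean", "single", "max"),
                               masses = NULL) {
  kind <- match.arg(kind)
  combine <- match.arg(combine)
  if (is.null(dim(anchors))) anchors <- matrix(anchors, nrow = 1)
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 1) stop("metric needs at least one anchor")
  if (is.null(masses)) masses <- rep(1, nrow(anchors))
  stopifnot(length(masses) == nrow(anchors), all(masses > 0))
  structure(list(kind = kind, anchors = anchors, combine = combine,
                 masses = masses),
            class = "supervision_metric")
}

#' Evaluate a supervision metric on positions
#'
#' @param metric A `supervision_metric`.
#' @param positions Matrix of positions (frames in rows) or a single vector.
#' @return Numeric vector of metric values, one per frame.
#' @export
eval_metric <- function(metric, positions) {
  stopifnot(inherits(metric, "supervision_metric"))
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  positions <- as.matrix(positions)
  if (ncol(positions) != ncol(metric$anchors))
    stop("metric anchors and positions have different dimensionality")
  if (metric$kind == "com_distance") {
    cen <- colSums(metric$anchors * metric$masses) / sum(metric$masses)
    sqrt(rowSums(sweep(positions, 2, cen)^2))
  } else {
    d <- sapply(seq_len(nrow(metric$anchors)), function(i)
      sqrt(rowSums(sweep(positions, 2, metric$anchors[i, ])^2)))
    d <- matrix(d, nrow = nrow(positions))
    switch(metric$combine,
           single = d[, 1],
           mean = rowMeans(d),
           max = apply(d, 1, max))
  }
}

#' Supervision configuration
#'
#' Controls the supervised-sampling loop: window length, the stuck-escape
#' rule (after `max_consecutive_failures` straight rejections a longer
#' unsupervised segment of `escape_multiplier` windows is run and its final
#' state adopted unconditionally), the staged metric plan with its
#' switch-off thresholds, and the overall window budget.
#'
#' @param stage_plan List of stages, each `list(metric =, threshold =)`;
#'   thresholds must be strictly decreasing across stages. Supervision
#'   switches off (outcome "bound") when the final stage's threshold is
#'   reached.
#' @param window_duration Length of one supervised window (toy time).
#' @param max_consecutive_failures Rejections tolerated before an escape
#'   segment, default 10.
#' @param escape_multiplier Escape segment length in window multiples,
#'   default 5.
#' @param max_total_windows Window budget before outcome "exhausted".
#' @param seed Optional integer seed for the replica's RNG stream.
#' @return A `supervision_config`.
#' @export
supervision_config <- function(stage_plan, window_duration = 0.2,
                               max_consecutive_failures = 10L,
                               escape_multiplier = 5L,
                               max_total_windows = 20000L, seed = NULL) {
  stopifnot(window_duration > 0, max_consecutive_failures >= 1,
            escape_multiplier >= 1, max_total_windows >= 1,
            length(stage_plan) >= 1)
  thr <- vapply(stage_plan, function(s) s$threshold, numeric(1))
  if (any(thr <= 0)) stop("stage thresholds must be > 0")
  if (length(thr) > 1 && any(diff(thr) >= 0))
    stop("stage thresholds must be strictly decreasing")
  for (s in stage_plan) stopifnot(inherits(s$metric, "supervision_metric"))
  structure(list(stage_plan = stage_plan, window_duration = window_duration,
                 max_consecutive_failures = as.integer(max_consecutive_failures),
                 escape_multiplier = as.integer(escape_multiplier),
                 max_total_windows = as.integer(max_total_windows),
                 seed = seed),
            class = "supervision_config")
}

#' Default two-stage plan for a funnel landscape
#'
#' Stage 1 watches the particle-to-pocket-center distance down to
#' `2 * well_width`; stage 2 watches the mean distance to two anchor points
#' at `center +/- 0.25 * well_width` (the toy analog of gating on two key
#' atom pairs) down to the final threshold `0.5 * well_width`.
#'
#' @param spec A `funnel_landscape_spec`.
#' @return A two-element stage plan usable in [supervision_config()].
#' @export
default_stage_plan <- function(spec) {
  stopifnot(inherits(spec, "funnel_landscape_spec"))
  w <- spec$well_width
  off <- rep(0, spec$dimension); off[1] <- 0.25 * w
  list(
    list(metric = supervision_metric("com_distance",
                                     anchors = spec$well_center),
         threshold = 2 * w),
    list(metric = supervision_metric("pair_distance_set",
                                     anchors = rbind(spec$well_center + off,
                                                     spec$well_center - off),
                                     combine = "mean"),
         threshold = 0.5 * w)
  )
}

#' Toy supervised-sampling system
#'
#' Bundles a potential field with the ligand's start state.
#'
#' @param field A `potential_field` (typically from [gen_landscape()]).
#' @param state Optional starting `toy_state`; defaults to the landscape's
#'   start position at rest.
#' @return A `toy_system`.
#' @export
toy_system <- function(field, state = NULL) {
  stopifnot(inherits(field, "potential_field"))
  if (is.null(state)) {
    if (is.null(field$start_position))
      stop("field has no start position; supply `state`")
    state <- toy_state(field$start_position)
  }
  structure(list(field = field, state = state), class = "toy_system")
}

#' Least-squares slope of distance versus time
#'
#' The supervision acceptance statistic: the ordinary least-squares slope of
#' the metric samples within one window.
#'
#' @param samples Two-column matrix/data frame `(time, distance)`, or a list
#'   with `time` and `distance` elements.
#' @return The fitted slope (distance per time).
#' @export
fit_slope <- function(samples) {
  if (is.list(samples) && !is.data.frame(samples)) {
    t <- samples$time; d <- samples$distance
  } else {
    samples <- as.matrix(samples)
    t <- samples[, 1]; d <- samples[, 2]
  }
  if (length(t) < 2) stop("need at least 2 samples to fit a slope")
  if (max(t) == min(t)) stop("degenerate design: all times equal")
  fit <- stats::lm.fit(cbind(1, t), d)
  unname(fit$coefficients[2])
}

#' Run one supervised window
#'
#' Advances one window from `state`, evaluates `metric` on the start point
#' and every stored frame, fits the least-squares slope of metric versus
#' time and decides: accept iff slope < 0 (a zero slope counts as a
#' failure). On accept the returned candidate state — coordinates,
#' velocities and RNG token — is the next initial state; on reject the
#' caller restarts from its previous state with fresh noise.
#'
#' @param state A `toy_state`.
#' @param field A `potential_field`.
#' @param integrator An `integrator_config`.
#' @param metric A `supervision_metric`.
#' @param window_duration Window length (toy time).
#' @return `list(candidate_state, trajectory, samples, slope, decision)`.
#' @export
supervise_window <- function(state, field, integrator, metric,
                             window_duration) {
  n_steps <- max(integrator$stride,
                 as.integer(round(window_duration / integrator$timestep)))
  res <- advance(state, field, integrator, n_steps)
  vals <- eval_metric(metric, rbind(state$position, res$trajectory$coords))
  times <- c(state$time, res$trajectory$times)
  slope <- fit_slope(list(time = times, distance = vals))
  list(candidate_state = res$state, trajectory = res$trajectory,
       samples = data.frame(time = times, distance = vals),
       slope = slope,
       decision = if (slope < 0) "accept" else "reject")
}

#' Run the supervised-sampling algorithm
#'
#' Iterates supervised windows from the system's start state. Windows with a
#' negative metric slope are accepted and chained (coordinates, velocities
#' and RNG state); rejected windows are discarded and the run restarts from
#' the last accepted state with fresh noise. After
#' `max_consecutive_failures` straight rejections one unsupervised escape
#' segment of `escape_multiplier` windows is run and its final state adopted
#' unconditionally. The stage plan advances when the active stage's
#' threshold is reached; reaching the final threshold switches supervision
#' off with outcome `"bound"`; exceeding `max_total_windows` gives
#' `"exhausted"`.
#'
#' @param system A `toy_system`.
#' @param config A `supervision_config`.
#' @param integrator An `integrator_config`, default overdamped defaults.
#' @return List with `trajectory` (accepted path), `log` (one row per
#'   window/escape), `outcome`, `first_passage_time` (total simulated time
#'   at binding, `NA` if exhausted), `simulated_time`, `discarded_time`,
#'   `final_state`.
#' @export
run_sumd <- function(system, config, integrator = integrator_config()) {
  stopifnot(inherits(system, "toy_system"),
            inherits(config, "supervision_config"))
  field <- system$field
  state <- system$state
  if (is.null(state$rng_state)) {
    if (!is.null(config$seed)) set.seed(config$seed)
    state$rng_state <- get_rng_token()
  }
  n_stages <- length(config$stage_plan)
  stage <- 1L
  # a stage counts as satisfied when ITS OWN metric is at/below threshold
  cur_val <- function(st, sg)
    eval_metric(config$stage_plan[[sg]]$metric, st$position)
  while (stage <= n_stages &&
         cur_val(state, stage) <= config$stage_plan[[stage]]$threshold)
    stage <- stage + 1L

  log_rows <- list()
  traj_parts <- list()
  windows_used <- 0L
  failures <- 0L
  sim_time <- 0
  disc_time <- 0
  bound <- stage > n_stages
  fpt <- if (bound) 0 else NA_real_

  while (!bound && windows_used < config$max_total_windows) {
    metric <- config$stage_plan[[stage]]$metric
    w <- supervise_window(state, field, integrator, metric,
                          config$window_duration)
    windows_used <- windows_used + 1L
    sim_time <- sim_time + config$window_duration
    accepted <- w$decision == "accept"
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      window = windows_used, stage = stage,
      metric_start = w$samples$distance[1],
      metric_end = w$samples$distance[nrow(w$samples)],
      slope = w$slope, decision = w$decision,
      sim_time = sim_time, discarded_time = NA_real_)
    if (accepted) {
      failures <- 0L
      traj_parts[[length(traj_parts) + 1L]] <- w$trajectory
      state <- w$candidate_state
    } else {
      failures <- failures + 1L
      disc_time <- disc_time + config$window_duration
      # restart from the previous accepted state but with fresh noise:
      # the rejected window consumed RNG draws, carry the stream forward
      state$rng_state <- w$candidate_state$rng_state
      if (failures >= config$max_consecutive_failures) {
        n_esc <- max(integrator$stride, as.integer(round(
          config$escape_multiplier * config$window_duration /
            integrator$timestep)))
        esc <- advance(state, field, integrator, n_esc)
        windows_used <- windows_used + config$escape_multiplier
        sim_time <- sim_time +
          config$escape_multiplier * config$window_duration
        vals <- eval_metric(metric,
                            rbind(state$position, esc$trajectory$coords))
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          window = windows_used, stage = stage,
          metric_start = vals[1], metric_end = vals[length(vals)],
          slope = NA_real_, decision = "escape",
          sim_time = sim_time, discarded_time = NA_real_)
        traj_parts[[length(traj_parts) + 1L]] <- esc$trajectory
        state <- esc$state
        failures <- 0L
      }
    }
    while (stage <= n_stages &&
           cur_val(state, stage) <= config$stage_plan[[stage]]$threshold)
      stage <- stage + 1L
    if (stage > n_stages) {
      bound <- TRUE
      fpt <- sim_time
    }
  }

  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(window = integer(), stage = integer(),
               metric_start = numeric(), metric_end = numeric(),
               slope = numeric(), decision = character(),
               sim_time = numeric(), discarded_time = numeric())
  log$discarded_time <- cumsum(
    ifelse(log$decision == "reject", config$window_duration, 0))
  traj <- if (length(traj_parts)) bind_trajectories(traj_parts) else
    new_trajectory(numeric(0),
                   matrix(numeric(0), ncol = field$dimension),
                   integrator$stride, integrator$timestep)
  structure(list(trajectory = traj, log = log,
                 outcome = if (bound) "bound" else "exhausted",
                 first_passage_time = fpt, simulated_time = sim_time,
                 discarded_time = disc_time, final_state = state,
                 n_windows = windows_used),
            class = "sumd_result")
}

#' @export
print.sumd_result <- function(x, ...) {
  cat("<sumd_result>", x$outcome, "| windows:", x$n_windows,
      "| simulated time:", signif(x$simulated_time, 4),
      "| discarded:", signif(x$discarded_time, 4), "\n")
  invisible(x)
}

#' Run a swarm of supervised replicas
#'
#' Runs `n_replicas` independent seeded replicas and returns the first
#' `select_first_k` (by replica index) whose outcome is `"bound"`. If fewer
#' than `select_first_k` bind, a warning is raised and all bound replicas
#' are returned.
#'
#' @param system A `toy_system`.
#' @param config A `supervision_config`; its seed acts as the base seed.
#' @param n_replicas Number of replicas (>= `select_first_k`).
#' @param select_first_k Replicas to select among the bound ones.
#' @param integrator An `integrator_config`.
#' @return List with `selected` (the chosen `sumd_result`s, named by replica
#'   index), `outcomes` (all replica outcomes), `n_bound`, `seeds`.
#' @export
run_swarm <- function(system, config, n_replicas, select_first_k,
                      integrator = integrator_config()) {
  stopifnot(n_replicas >= select_first_k, select_first_k >= 1)
  base_seed <- if (is.null(config$seed)) 0L else config$seed
  seeds <- base_seed + seq_len(n_replicas)
  results <- vector("list", n_replicas)
  for (i in seq_len(n_replicas)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    results[[i]] <- run_sumd(system, cfg_i, integrator)
  }
  outcomes <- vapply(results, `[[`, character(1), "outcome")
  bound_idx <- which(outcomes == "bound")
  if (length(bound_idx) < select_first_k)
    warning(sprintf("only %d of %d replicas bound (requested %d)",
                    length(bound_idx), n_replicas, select_first_k))
  sel <- bound_idx[seq_len(min(select_first_k, length(bound_idx)))]
  list(selected = stats::setNames(results[sel], sel),
       outcomes = outcomes, n_bound = length(bound_idx), seeds = seeds,
       results = results)
}

#' Unsupervised first-passage time
#'
#' Plain dynamics from the system's start state until `metric` first drops
#' to `threshold` (checked at frame resolution), or until `max_time`. The
#' independent baseline against which the supervision speed-up is measured.
#'
#' @param system A `toy_system`.
#' @param integrator An `integrator_config`.
#' @param metric A `supervision_metric`.
#' @param threshold Binding threshold on the metric.
#' @param max_time Give-up time (toy time).
#' @param seed Optional seed for the replica.
#' @param chunk_steps Steps simulated per internal chunk.
#' @return List with `time` (first-passage time, `NA` if not reached within
#'   `max_time`), `bound` flag, `final_state`.
#' @export
first_passage <- function(system, integrator, metric, threshold, max_time,
                          seed = NULL, chunk_steps = 100000L) {
  state <- system$state
  if (is.null(state$rng_state)) {
    if (!is.null(seed)) set.seed(seed)
    state$rng_state <- get_rng_token()
  }
  if (eval_metric(metric, state$position) <= threshold)
    return(list(time = 0, bound = TRUE, final_state = state))
  t_done <- 0
  while (t_done < max_time) {
    n <- min(chunk_steps,
             max(integrator$stride,
                 ceiling((max_time - t_done) / integrator$timestep)))
    res <- advance(state, system$field, integrator, n)
    vals <- eval_metric(metric, res$trajectory$coords)
    hit <- which(vals <= threshold)
    if (length(hit)) {
      i <- hit[1]
      st <- toy_state(res$trajectory$coords[i, ],
                      time = res$trajectory$times[i],
                      rng_state = res$state$rng_state)
      return(list(time = res$trajectory$times[i] - system$state$time,
                  bound = TRUE, final_state = st))
    }
    state <- res$state
    t_done <- state$time - system$state$time
  }
  list(time = NA_real_, bound = FALSE, final_state = state)
}
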