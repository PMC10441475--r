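#' Rate parameters for the 1:1 Langmuir binding model
#'
#' `A + B <-> AB` with association rate `kon`, dissociation rate `koff` and
#' saturation response `Rmax`. All rates in SI units (M^-1 s^-1, s^-1), the
#' response in RU.
#'
#' @param kon Association rate constant, M^-1 s^-1.
#' @param koff Dissociation rate constant, s^-1.
#' @param Rmax Saturation response, RU.
#' @return A `one_to_one_params`.
#' @export
one_to_one_params <- function(kon, koff, Rmax) {
  stopifnot(kon > 0, koff > 0, Rmax > 0,
            is.finite(kon), is.finite(koff), is.finite(Rmax))
  structure(list(kon = kon, koff = koff, Rmax = Rmax),
            class = "one_to_one_params")
}

#' Rate parameters for the two-state reaction model
#'
#' `A + B <-> AB <-> AB*`: a binding step (`kon1` in M^-1 s^-1, `koff1` in
#' s^-1) followed by a concentration-independent conformational change
#' (`kon2`, `koff2`, both s^-1). `kon2 = 0` is admitted and reduces the
#' model to 1:1 binding. Note the conformational step's forward rate is a
#' first-order rate even where instrument reports print it with
#' second-order units; only with `kon2` in s^-1 does the model's
#' equilibrium algebra reproduce the reported dissociation constants.
#'
#' @param kon1 Binding rate, M^-1 s^-1.
#' @param koff1 Unbinding rate, s^-1.
#' @param kon2 Forward conformational rate, s^-1 (>= 0).
#' @param koff2 Reverse conformational rate, s^-1.
#' @param Rmax Saturation response, RU.
#' @return A `two_state_params`.
#' @export
two_state_params <- function(kon1, koff1, kon2, koff2, Rmax) {
  stopifnot(kon1 > 0, koff1 > 0, kon2 >= 0, koff2 > 0, Rmax > 0,
            all(is.finite(c(kon1, koff1, kon2, koff2, Rmax))))
  structure(list(kon1 = kon1, koff1 = koff1, kon2 = kon2, koff2 = koff2,
                 Rmax = Rmax),
            class = "two_state_params")
}

#' Equilibrium dissociation constant of the 1:1 model
#'
#' `KD = koff / kon`, reported in nM.
#'
#' @param p A `one_to_one_params`.
#' @return KD in nM.
#' @export
kd_one_to_one <- function(p) {
  stopifnot(inherits(p, "one_to_one_params"))
  p$koff / p$kon * 1e9
}

#' Equilibrium dissociation constant of the two-state model
#'
#' For `A + B <-> AB <-> AB*` the overall equilibrium dissociation constant
#' is `KD = (koff1 / kon1) * koff2 / (kon2 + koff2)`: the binding-step KD
#' discounted by the fraction of complex pulled into the second state.
#' Reported in nM.
#'
#' @param p A `two_state_params`.
#' @return KD in nM.
#' @export
kd_two_state <- function(p) {
  stopifnot(inherits(p, "two_state_params"))
  (p$koff1 / p$kon1) * p$koff2 / (p$kon2 + p$koff2) * 1e9
}

#' Single-cycle injection schedule
#'
#' An ascending analyte concentration series injected without surface
#' regeneration: each injection associates for `association_s` seconds and
#' dissociates for `inter_dissociation_s`, except the last, which
#' dissociates for `final_dissociation_s`.
#'
#' @param concentrations_M Strictly positive analyte concentrations (M);
#'   must be non-decreasing in single-cycle mode.
#' @param association_s Association time per injection (s).
#' @param inter_dissociation_s Dissociation time between injections (s).
#' @param final_dissociation_s Dissociation time after the last injection.
#' @param sample_rate Sampling rate (Hz).
#' @return An `injection_schedule`.
#' @export
injection_schedule <- function(concentrations_M,
                               association_s = 120,
                               inter_dissociation_s = 120,
                               final_dissociation_s = 1200,
                               sample_rate = 10) {
  stopifnot(length(concentrations_M) >= 1, all(concentrations_M >= 0),
            association_s > 0, inter_dissociation_s >= 0,
            final_dissociation_s >= 0, sample_rate > 0)
  if (any(diff(concentrations_M) < 0))
    stop("single-cycle concentrations must be non-decreasing")
  structure(list(concentrations_M = concentrations_M,
                 association_s = association_s,
                 inter_dissociation_s = inter_dissociation_s,
                 final_dissociation_s = final_dissociation_s,
                 sample_rate = sample_rate),
            class = "injection_schedule")
}

#' The standard five-point single-cycle schedule
#'
#' Five-fold dilution series 2.4, 12, 60, 300, 1500 nM; 120 s association
#' and 120 s inter-injection dissociation per injection, 1200 s final
#' dissociation, sampled at 10 Hz.
#'
#' @param sample_rate Sampling rate (Hz), default 10.
#' @return An `injection_schedule`.
#' @export
single_cycle_schedule <- function(sample_rate = 10) {
  injection_schedule(c(2.4, 12, 60, 300, 1500) * 1e-9,
                     sample_rate = sample_rate)
}

# phase table: one row per constant-concentration interval
schedule_phases <- function(schedule) {
  n <- length(schedule$concentrations_M)
  conc <- numeric(0); dur <- numeric(0); lab <- character(0)
  for (i in seq_len(n)) {
    conc <- c(conc, schedule$concentrations_M[i])
    dur <- c(dur, schedule$association_s)
    lab <- c(lab, sprintf("assoc_%d", i))
    d <- if (i < n) schedule$inter_dissociation_s else
      schedule$final_dissociation_s
    if (d > 0) {
      conc <- c(conc, 0)
      dur <- c(dur, d)
      lab <- c(lab, sprintf("dissoc_%d", i))
    }
  }
  data.frame(conc = conc, duration = dur, phase = lab,
             start = cumsum(c(0, dur[-length(dur)])),
             end = cumsum(dur))
}

# 1:1 model state propagation: returns R(t_rel) from R0 at constant C
one_to_one_phase <- function(R0, C, t_rel, p) {
  kobs <- p$kon * C + p$koff
  Req <- if (kobs > 0) p$kon * C * p$Rmax / kobs else 0
  Req + (R0 - Req) * exp(-kobs * t_rel)
}

# Two-state propagation of x = (AB, AB*) at constant C, vectorized in
# t_rel. The phase is the affine-linear system x' = A x + b with
#   A = [[-(kon1 C + koff1 + kon2), koff2 - kon1 C], [kon2, -koff2]]
# (the kon1 C term in A[1,2] comes from site conservation Rmax - AB - AB*),
# b = (kon1 C Rmax, 0). Solved exactly via the closed-form 2x2 matrix
# exponential e^{At} = e^{mu t} (cosh(qt) I + sinh(qt)/q (A - mu I)) with
# mu = tr/2, q = sqrt(disc)/2; the cos/sin branch covers disc < 0.
two_state_phase <- function(x0, C, t_rel, p) {
  a11 <- -(p$kon1 * C + p$koff1 + p$kon2)
  a12 <- p$koff2 - p$kon1 * C
  a21 <- p$kon2
  a22 <- -p$koff2
  b1 <- p$kon1 * C * p$Rmax
  # det(A) = koff2 kon1 C + koff1 koff2 + kon2 kon1 C > 0 always
  det_ <- a11 * a22 - a12 * a21
  xss <- c(-a22 * b1 / det_, a21 * b1 / det_)
  d0 <- x0 - xss
  mu <- (a11 + a22) / 2
  disc <- (a11 - a22)^2 + 4 * a12 * a21
  q <- sqrt(abs(disc)) / 2
  qt <- q * t_rel
  if (disc >= 0) {
    # e^{mu t} cosh(qt) and e^{mu t} sinh(qt)/q via the stable eigenvalues
    # l = mu +/- q (both <= 0), avoiding cosh overflow on long phases
    e1 <- exp((mu + q) * t_rel)
    e2 <- exp((mu - q) * t_rel)
    ech <- (e1 + e2) / 2
    esh <- ifelse(qt > 1e-6, (e1 - e2) / (2 * q),
                  t_rel * exp(mu * t_rel) * (1 + qt^2 / 6))
  } else {
    emu <- exp(mu * t_rel)
    ech <- emu * cos(qt)
    esh <- emu * ifelse(qt > 1e-6, sin(qt) / q, t_rel * (1 - qt^2 / 6))
  }
  AB <- xss[1] + ech * d0[1] + esh * ((a11 - mu) * d0[1] + a12 * d0[2])
  ABs <- xss[2] + ech * d0[2] + esh * (a21 * d0[1] + (a22 - mu) * d0[2])
  cbind(AB = AB, ABstar = ABs)
}

# evaluate a kinetic model at arbitrary times over a schedule
eval_kinetic_model <- function(params, schedule, times, components = FALSE) {
  phases <- schedule_phases(schedule)
  two_state <- inherits(params, "two_state_params")
  state <- if (two_state) c(0, 0) else 0
  out <- numeric(length(times))
  comp <- if (two_state && components)
    matrix(0, length(times), 2, dimnames = list(NULL, c("AB", "ABstar")))
  for (i in seq_len(nrow(phases))) {
    # times strictly inside (start, end]; t = 0 keeps the initial state
    sel <- which(times > phases$start[i] & times <= phases$end[i] + 1e-12)
    t_rel <- times[sel] - phases$start[i]
    if (two_state) {
      if (length(sel)) {
        x <- two_state_phase(state, phases$conc[i], t_rel, params)
        out[sel] <- x[, 1] + x[, 2]
        if (components) comp[sel, ] <- x
      }
      state <- as.numeric(two_state_phase(state, phases$conc[i],
                                          phases$duration[i], params))
    } else {
      if (length(sel))
        out[sel] <- one_to_one_phase(state, phases$conc[i], t_rel, params)
      state <- one_to_one_phase(state, phases$conc[i], phases$duration[i],
                                params)
    }
  }
  if (!all(is.finite(out)))
    stop("kinetic simulation produced non-finite response (params: ",
         paste(signif(unlist(unclass(params)), 4), collapse = ", "), ")")
  if (two_state && components) attr(out, "components") <- comp
  out
}

conc_at_times <- function(schedule, times) {
  phases <- schedule_phases(schedule)
  conc <- numeric(length(times))
  for (i in seq_len(nrow(phases))) {
    sel <- times > phases$start[i] & times <= phases$end[i] + 1e-12
    conc[sel] <- phases$conc[i]
  }
  conc
}

phase_at_times <- function(schedule, times) {
  phases <- schedule_phases(schedule)
  lab <- rep("baseline", length(times))
  for (i in seq_len(nrow(phases))) {
    sel <- times > phases$start[i] & times <= phases$end[i] + 1e-12
    lab[sel] <- phases$phase[i]
  }
  lab
}

new_sensorgram <- function(times, response, schedule, ligand_label = "",
                           analyte_label = "", capture_level = NA_real_,
                           metadata = list()) {
  stopifnot(all(diff(times) > 0), all(is.finite(response)))
  df <- data.frame(time_s = times, response_RU = response,
                   conc_M = conc_at_times(schedule, times),
                   phase = phase_at_times(schedule, times))
  structure(list(data = df, schedule = schedule,
                 ligand_label = ligand_label, analyte_label = analyte_label,
                 capture_level = capture_level, metadata = metadata),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat("<sensorgram>", nrow(x$data), "points,",
      length(x$schedule$concentrations_M), "injections",
      sprintf("(%.3g-%.3g nM),", min(x$schedule$concentrations_M) * 1e9,
              max(x$schedule$concentrations_M) * 1e9),
      "max response", signif(max(x$data$response_RU), 4), "RU\n")
  invisible(x)
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Integrates `dR/dt = kon C(t) (Rmax - R) - koff R` piecewise-analytically
#' over the injection schedule (each constant-concentration phase has the
#' closed-form mono-exponential solution), with the response continuous
#' across phase boundaries.
#'
#' @param p A `one_to_one_params`.
#' @param schedule An `injection_schedule`.
#' @param times Optional explicit sample times; defaults to the schedule's
#'   uniform grid at `sample_rate`.
#' @return A `sensorgram` (noise-free).
#' @export
simulate_one_to_one <- function(p, schedule, times = NULL) {
  stopifnot(inherits(p, "one_to_one_params"),
            inherits(schedule, "injection_schedule"))
  if (is.null(times)) times <- schedule_grid(schedule)
  r <- eval_kinetic_model(p, schedule, times)
  new_sensorgram(times, r, schedule,
                 metadata = list(model = "one_to_one", true_params = p))
}

#' Simulate a two-state reaction sensorgram
#'
#' Integrates the coupled system
#' `d[AB]/dt  = kon1 C (Rmax - AB - AB*) - koff1 AB - kon2 AB + koff2 AB*`,
#' `d[AB*]/dt = kon2 AB - koff2 AB*`, response `R = AB + AB*`. Each
#' constant-concentration phase is linear, so it is solved exactly by
#' eigen-decomposition of the 2x2 rate matrix (real, distinct eigenvalues
#' for positive rates); states are continuous across phase boundaries.
#'
#' @param p A `two_state_params`.
#' @param schedule An `injection_schedule`.
#' @param times Optional explicit sample times.
#' @return A `sensorgram` with the species series in
#'   `metadata$components`.
#' @export
simulate_two_state <- function(p, schedule, times = NULL) {
  stopifnot(inherits(p, "two_state_params"),
            inherits(schedule, "injection_schedule"))
  if (is.null(times)) times <- schedule_grid(schedule)
  r <- eval_kinetic_model(p, schedule, times, components = TRUE)
  comp <- attr(r, "components")
  attr(r, "components") <- NULL
  new_sensorgram(times, as.numeric(r), schedule,
                 metadata = list(model = "two_state", true_params = p,
                                 components = comp))
}

schedule_grid <- function(schedule) {
  phases <- schedule_phases(schedule)
  total <- phases$end[nrow(phases)]
  seq(1 / schedule$sample_rate, total, by = 1 / schedule$sample_rate)
}

#' Fit a kinetic model to a sensorgram
#'
#' Nonlinear least squares (Levenberg-Marquardt, `minpack.lm`) of the 1:1
#' or two-state forward model to the full single-cycle trace. Rate
#' constants and Rmax are fitted in log space (positivity; rates span
#' orders of magnitude), with a data-driven first start plus seeded random
#' multistarts to guard against the two-state model's local minima.
#' Non-convergence is reported in the result, not raised.
#'
#' @param sg A `sensorgram`.
#' @param model "one_to_one" or "two_state".
#' @param n_starts Number of starts (1 data-driven + the rest random).
#' @param seed Seed for the random starts.
#' @param weights Optional per-point weights for the residuals.
#' @param decimate Keep every k-th point before fitting (1 = all points).
#' @return A `binding_fit`: fitted params (natural units), `derived_kd_nM`,
#'   `residual_sse`, per-parameter `stderr`, `n_points`, `converged`.
#' @export
fit_sensorgram <- function(sg, model = c("one_to_one", "two_state"),
                           n_starts = 8, seed = 1, weights = NULL,
                           decimate = 1L) {
  stopifnot(inherits(sg, "sensorgram"))
  model <- match.arg(model)
  if (all(conc_at_times(sg$schedule, sg$data$time_s) == 0))
    stop("schedule has no nonzero-concentration association phase")
  keep <- seq(1, nrow(sg$data), by = as.integer(decimate))
  times <- sg$data$time_s[keep]
  resp <- sg$data$response_RU[keep]
  w <- if (is.null(weights)) rep(1, length(keep)) else weights[keep]
  schedule <- sg$schedule

  make_params <- function(logp) {
    p <- exp(logp)
    if (model == "one_to_one")
      one_to_one_params(p[1], p[2], p[3])
    else
      two_state_params(p[1], p[2], p[3], p[4], p[5])
  }
  resid_fn <- function(logp) {
    pr <- tryCatch(make_params(logp), error = function(e) NULL)
    if (is.null(pr)) return(rep(1e6, length(resp)))
    sim <- tryCatch(eval_kinetic_model(pr, schedule, times),
                    error = function(e) NULL)
    if (is.null(sim)) return(rep(1e6, length(resp)))
    (sim - resp) * sqrt(w)
  }

  starts <- fit_starts(model, times, resp, schedule, n_starts, seed)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(model = model, params = NULL,
                          derived_kd_nM = NA_real_,
                          residual_sse = NA_real_, stderr = NULL,
                          n_points = length(resp), converged = FALSE,
                          message = "all starts failed"),
                     class = "binding_fit"))
  pfit <- make_params(best$par)
  kd <- if (model == "one_to_one") kd_one_to_one(pfit) else kd_two_state(pfit)
  se <- fit_stderr(best, resid_fn, length(resp))
  pv <- unlist(unclass(pfit))
  names(se) <- names(pv)
  converged <- best$info %in% 1:4
  structure(list(model = model, params = pfit, derived_kd_nM = kd,
                 residual_sse = best$deviance,
                 stderr = pv * se,  # delta method from log space
                 n_points = length(resp), converged = converged,
                 message = best$message),
            class = "binding_fit")
}

fit_starts <- function(model, times, resp, schedule, n_starts, seed) {
  rmax0 <- max(resp, 1) * 1.2
  # decay rate from the final dissociation tail
  phases <- schedule_phases(schedule)
  last <- phases[nrow(phases), ]
  tail_sel <- times > last$start & resp > max(resp) * 0.02
  koff0 <- 1e-2
  if (last$conc == 0 && sum(tail_sel) > 10) {
    sl <- tryCatch(stats::lm.fit(cbind(1, times[tail_sel]),
                                 log(resp[tail_sel]))$coefficients[2],
                   error = function(e) NA)
    if (is.finite(sl) && sl < 0) koff0 <- min(max(-sl, 1e-4), 1)
  }
  cmid <- stats::median(phases$conc[phases$conc > 0])
  kon0 <- koff0 / cmid
  base <- if (model == "one_to_one") log(c(kon0, koff0, rmax0)) else
    log(c(kon0, koff0, 5e-3, 1e-3, rmax0))
  starts <- list(base)
  if (n_starts > 1) {
    rng <- local({set.seed(seed); lapply(seq_len(n_starts - 1), function(i)
      stats::runif(length(base), -1.5, 1.5))})
    for (r in rng) starts[[length(starts) + 1L]] <- base + r * log(10) / 1.5
  }
  starts
}

fit_stderr <- function(fit, resid_fn, n) {
  p <- length(fit$par)
  se <- rep(NA_real_, p)
  if (n <= p) return(se)
  J <- tryCatch({
    eps <- 1e-6
    r0 <- resid_fn(fit$par)
    sapply(seq_len(p), function(i) {
      d <- fit$par; d[i] <- d[i] + eps
      (resid_fn(d) - r0) / eps
    })
  }, error = function(e) NULL)
  if (is.null(J)) return(se)
  s2 <- fit$deviance / (n - p)
  cv <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  se
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit>", x$model,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$params)) {
    pv <- unlist(unclass(x$params))
    for (nm in names(pv))
      cat(sprintf("  %-6s %.4g", nm, pv[nm]),
          if (!is.null(x$stderr) && is.finite(x$stderr[nm]))
            sprintf(" (se %.2g)", x$stderr[nm]) else "", "\n", sep = "")
    cat(sprintf("  KD     %.4g nM\n", x$derived_kd_nM))
    cat(sprintf("  SSE    %.4g RU^2 over %d points\n",
                x$residual_sse, x$n_points))
  }
  invisible(x)
}

#' Fold change between two positive quantities
#'
#' Ratio of the larger to the smaller, optionally rounded to significant
#' figures — the convention used when quoting affinity or off-rate
#' differences ("x-fold tighter/faster").
#'
#' @param a,b Positive values (e.g. two KDs in the same unit).
#' @param sig_digits Significant figures for rounding; NULL for exact.
#' @return The fold change (>= 1).
#' @export
fold_change <- function(a, b, sig_digits = 2) {
  stopifnot(a > 0, b > 0)
  f <- max(a, b) / min(a, b)
  if (is.null(sig_digits)) f else signif(f, sig_digits)
}
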