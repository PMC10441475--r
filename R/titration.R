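#' Titration curve container
#'
#' Concentration-signal pairs from a saturation assay (fluorescence
#' polarization one-site binding, or steady-state Michaelis-Menten
#' velocities), possibly with replicates.
#'
#' @param conc_M Concentrations (M), positive.
#' @param signal Measured signal, same length.
#' @param replicate Integer replicate id per point, default all 1.
#' @param metadata Optional list (true parameters for synthetic curves).
#' @return A `titration_curve`.
#' @export
titration_curve <- function(conc_M, signal, replicate = NULL,
                            metadata = list()) {
  stopifnot(length(conc_M) == length(signal), all(conc_M > 0),
            all(is.finite(signal)))
  if (is.null(replicate)) replicate <- rep(1L, length(conc_M))
  structure(list(data = data.frame(conc_M = conc_M, signal = signal,
                                   replicate = as.integer(replicate)),
                 metadata = metadata),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("<titration_curve>", nrow(x$data), "points,",
      length(unique(x$data$replicate)), "replicate(s), conc",
      sprintf("%.3g-%.3g nM\n", min(x$data$conc_M) * 1e9,
              max(x$data$conc_M) * 1e9))
  invisible(x)
}

# shared hyperbolic fit: Y = amp * X / (K + X); returns c(amp, K) or NULL
fit_hyperbola <- function(x, y) {
  if (length(unique(x)) < 3) stop("need >= 3 distinct concentrations")
  if (stats::sd(y) == 0) return(NULL)  # no curvature to fit
  amp0 <- max(y) * 1.1
  half <- which.min(abs(y - amp0 / 2))
  k0 <- max(x[half], min(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ amp * x / (k + x),
                      start = list(amp = amp0, k = k0),
                      lower = c(1e-12, 1e-15),
                      control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  fit
}

fit_saturation <- function(curve, names_out, model_label) {
  stopifnot(inherits(curve, "titration_curve"))
  reps <- sort(unique(curve$data$replicate))
  per <- lapply(reps, function(r) {
    d <- curve$data[curve$data$replicate == r, ]
    fit <- fit_hyperbola(d$conc_M, d$signal)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 2))
    list(amp = unname(cf["amp"]), k = unname(cf["k"]),
         se = unname(se), sse = sum(stats::resid(fit)^2),
         n = nrow(d))
  })
  ok <- !vapply(per, is.null, logical(1))
  if (!any(ok))
    return(structure(list(model = model_label, params = NULL,
                          converged = FALSE,
                          message = "no curvature: all signals equal"),
                     class = "binding_fit"))
  per <- per[ok]
  amps <- vapply(per, `[[`, numeric(1), "amp")
  ks <- vapply(per, `[[`, numeric(1), "k")
  params <- stats::setNames(c(mean(amps), mean(ks)), names_out)
  out <- list(model = model_label, params = params,
              derived_kd_nM = mean(ks) * 1e9,
              params_sd = stats::setNames(
                c(if (length(per) > 1) stats::sd(amps) else NA_real_,
                  if (length(per) > 1) stats::sd(ks) else NA_real_),
                names_out),
              stderr = stats::setNames(per[[1]]$se, names_out),
              per_replicate = data.frame(
                replicate = reps[ok],
                amplitude = amps, k_M = ks, k_nM = ks * 1e9),
              residual_sse = sum(vapply(per, `[[`, numeric(1), "sse")),
              n_points = nrow(curve$data), converged = TRUE)
  structure(out, class = "binding_fit")
}

#' Fit a one-site specific binding isotherm
#'
#' `Y = Bmax * X / (Kd + X)` with X the protein concentration and Y the
#' specific binding signal. Replicates are fitted independently; the
#' reported Kd and Bmax are the replicate means with their standard
#' deviations (`params_sd`), following the usual n = 3 convention.
#'
#' @param curve A `titration_curve`.
#' @return A `binding_fit` with `params` (Bmax, Kd in M), `derived_kd_nM`,
#'   and the per-replicate table.
#' @export
fit_one_site <- function(curve) {
  fit_saturation(curve, c("Bmax", "Kd"), "one_site")
}

#' Fit a Michaelis-Menten saturation curve
#'
#' `Y = Vmax * X / (Km + X)`; identical numerics to [fit_one_site()] with
#' enzyme-kinetics naming (here X is the titrated enzyme concentration and
#' Y the observed velocity, as in a base de-stacking fluorescence assay).
#'
#' @param curve A `titration_curve`.
#' @return A `binding_fit` with `params` (Vmax, Km in M).
#' @export
fit_michaelis_menten <- function(curve) {
  fit_saturation(curve, c("Vmax", "Km"), "michaelis_menten")
}
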