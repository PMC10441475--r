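#' Funnel binding-landscape specification
#'
#' Describes a toy binding landscape: a single attractive well (the "pocket")
#' on a flat background inside a reflecting box, optionally guarded by a
#' radial barrier shell. Energies are in units of kT, lengths are
#' dimensionless toy lengths. The well is a Gaussian truncated (and shifted
#' to continuity) at `5 * well_width`, so the background is exactly zero far
#' from the pocket.
#'
#' @param dimension Spatial dimension, 1-3.
#' @param well_center Numeric vector of length `dimension`; pocket location.
#' @param well_depth Well depth at the center, kT units; must be positive.
#' @param well_width Gaussian width of the well (toy length).
#' @param barrier_height Height of an optional radial Gaussian barrier shell
#'   (kT); 0 disables it.
#' @param barrier_radius Radius of the barrier shell; default `2 * well_width`.
#' @param barrier_width Width of the barrier shell; default `well_width / 2`.
#' @param start_position Numeric vector; where trajectories begin. Must be
#'   farther than `well_width` from the center.
#' @param box_half_width Half-width of the reflecting box; must contain both
#'   the start position and the well.
#' @return An object of class `funnel_landscape_spec`.
#' @seealso [gen_landscape()]
#' @export
funnel_landscape_spec <- function(dimension = 2,
                                  well_center = rep(0, dimension),
                                  well_depth = 8,
                                  well_width = 1,
                                  barrier_height = 0,
                                  barrier_radius = 2 * well_width,
                                  barrier_width = well_width / 2,
                                  start_position = c(8, rep(0, dimension - 1)),
                                  box_half_width = 10) {
  stopifnot(dimension %in% 1:3,
            length(well_center) == dimension,
            length(start_position) == dimension)
  vals <- c(well_center, well_depth, well_width, barrier_height,
            start_position, box_half_width)
  if (!all(is.finite(vals))) stop("landscape parameters must be finite")
  if (well_depth <= 0) stop("well_depth must be > 0")
  if (well_width <= 0) stop("well_width must be > 0")
  if (barrier_height < 0) stop("barrier_height must be >= 0")
  d_start <- sqrt(sum((start_position - well_center)^2))
  if (d_start <= well_width)
    stop("start_position must lie farther than well_width from well_center")
  if (any(abs(start_position) > box_half_width) ||
      any(abs(well_center) > box_half_width))
    stop("box must contain both start_position and well_center")
  structure(list(dimension = dimension, well_center = well_center,
                 well_depth = well_depth, well_width = well_width,
                 barrier_height = barrier_height,
                 barrier_radius = barrier_radius,
                 barrier_width = barrier_width,
                 start_position = start_position,
                 box_half_width = box_half_width),
            class = "funnel_landscape_spec")
}

#' Default 2D funnel landscape
#'
#' The package's reference landscape for supervised-sampling experiments:
#' a 2D well of depth 8 kT and width 1 at the origin, start at distance 8,
#' reflecting box of half-width 10. Deep enough that unsupervised binding is
#' rare on short runs but observable, so the supervision speed-up can be
#' measured.
#'
#' @return A `funnel_landscape_spec`.
#' @export
m6a_funnel <- function() funnel_landscape_spec()

#' Build a potential field from a landscape specification
#'
#' Returns a `potential_field`: callable potential/force closures plus the
#' parametric descriptor the compiled integrator consumes. Inside the
#' truncation radius `r_cut = 5 * well_width` the well is
#' `U(r) = -depth * (exp(-r^2 / (2 w^2)) - e_c) / (1 - e_c)` with
#' `e_c = exp(-r_cut^2 / (2 w^2))`, zero beyond, so `U(center) = -depth`
#' exactly and the background is exactly 0.
#'
#' @param spec A `funnel_landscape_spec`.
#' @return A `potential_field` with elements `potential(x)`, `force(x)`,
#'   `dimension`, `box_half_width`, `start_position`, and the descriptor.
#' @export
gen_landscape <- function(spec) {
  stopifnot(inherits(spec, "funnel_landscape_spec"))
  r_cut <- 5 * spec$well_width
  desc <- list(kind = "funnel", dimension = spec$dimension,
               box_half_width = spec$box_half_width,
               center = spec$well_center, well_depth = spec$well_depth,
               well_width = spec$well_width, r_cut = r_cut,
               barrier_height = spec$barrier_height,
               barrier_radius = spec$barrier_radius,
               barrier_width = spec$barrier_width)
  e_cut <- exp(-r_cut^2 / (2 * spec$well_width^2))
  potential <- function(x) {
    r2 <- sum((x - spec$well_center)^2)
    r <- sqrt(r2)
    u <- 0
    if (r < r_cut) {
      e <- exp(-r2 / (2 * spec$well_width^2))
      u <- -spec$well_depth * (e - e_cut) / (1 - e_cut)
    }
    if (spec$barrier_height > 0) {
      u <- u + spec$barrier_height *
        exp(-(r - spec$barrier_radius)^2 / (2 * spec$barrier_width^2))
    }
    u
  }
  force <- function(x) {
    dx <- x - spec$well_center
    r2 <- sum(dx^2)
    r <- sqrt(r2)
    f <- rep(0, spec$dimension)
    if (r < r_cut) {
      e <- exp(-r2 / (2 * spec$well_width^2))
      f <- f - spec$well_depth * e / ((1 - e_cut) * spec$well_width^2) * dx
    }
    if (spec$barrier_height > 0 && r > 1e-12) {
      dr <- r - spec$barrier_radius
      dudr <- -spec$barrier_height * dr / spec$barrier_width^2 *
        exp(-dr^2 / (2 * spec$barrier_width^2))
      f <- f - dudr * dx / r
    }
    f
  }
  new_potential_field(desc, potential, force,
                      start_position = spec$start_position, spec = spec)
}

#' @keywords internal
new_potential_field <- function(desc, potential, force,
                                start_position = NULL, spec = NULL) {
  structure(list(kind = desc$kind, dimension = desc$dimension,
                 box_half_width = desc$box_half_width,
                 descriptor = desc, potential = potential, force = force,
                 start_position = start_position, spec = spec),
            class = "potential_field")
}

#' Flat potential field
#'
#' @param dimension Spatial dimension.
#' @param box_half_width Reflecting-box half-width.
#' @return A `potential_field` with `U = 0` everywhere.
#' @export
flat_field <- function(dimension = 1, box_half_width = Inf) {
  desc <- list(kind = "flat", dimension = dimension,
               box_half_width = box_half_width)
  new_potential_field(desc,
                      potential = function(x) 0,
                      force = function(x) rep(0, dimension))
}

#' Harmonic potential field
#'
#' `U(x) = k/2 * |x - center|^2`, used for integrator validation against the
#' closed-form overdamped relaxation.
#'
#' @param k Spring constant (kT / length^2).
#' @param center Well center.
#' @param dimension Spatial dimension.
#' @param box_half_width Reflecting-box half-width.
#' @return A `potential_field`.
#' @export
harmonic_field <- function(k = 1, center = 0, dimension = length(center),
                           box_half_width = Inf) {
  desc <- list(kind = "harmonic", dimension = dimension,
               box_half_width = box_half_width, center = center, k = k)
  new_potential_field(desc,
                      potential = function(x) 0.5 * k * sum((x - center)^2),
                      force = function(x) -k * (x - center))
}

#' Quartic double-well field (1D)
#'
#' `U(x) = h * ((x / a)^2 - 1)^2`: minima at x = +/- a, barrier h at x = 0.
#' Used for the detailed-balance (Boltzmann histogram) check.
#'
#' @param height Barrier height h (kT).
#' @param scale Minima position a (toy length).
#' @param box_half_width Reflecting-box half-width.
#' @return A `potential_field`.
#' @export
double_well_field <- function(height = 2, scale = 1, box_half_width = 4) {
  desc <- list(kind = "double_well", dimension = 1L,
               box_half_width = box_half_width,
               height = height, scale = scale)
  new_potential_field(desc,
                      potential = function(x) {
                        s <- x[1] / scale
                        height * (s^2 - 1)^2
                      },
                      force = function(x) {
                        s <- x[1] / scale
                        -height * 4 * (s^2 - 1) * s / scale
                      })
}

#' @export
print.potential_field <- function(x, ...) {
  cat("<potential_field>", x$kind, sprintf("(%dD)", x$dimension),
      "box half-width:", x$box_half_width, "\n")
  invisible(x)
}
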