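test_that("center-of-mass distance matches hand geometry and is invariant", {
  expect_equal(com_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(com_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(com_distance(rbind(c(0, 0), c(2, 0)), c(10, 0),
                            masses_a = c(1, 3)), 8.5)
  expect_error(com_distance(matrix(numeric(0), 0, 2), c(0, 0)), "empty")
  # symmetry and rigid-motion invariance
  set.seed(1)
  a <- matrix(rnorm(6), 3, 2); b <- matrix(rnorm(6), 3, 2)
  expect_equal(com_distance(a, b), com_distance(b, a))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(3, -1)
  tr <- function(m) sweep(m %*% t(R), 2, -shift)
  expect_equal(com_distance(tr(a), tr(b)), com_distance(a, b),
               tolerance = 1e-12)
})

test_that("residence bookkeeping enumerates dwells correctly", {
  s_all <- data.frame(time = 1:4, value = c(0.1, 0.2, 0.1, 0.3))
  r <- residence(s_all, cutoff = 0.5)
  expect_equal(r$fraction_within, 1)
  expect_equal(r$n_entries, 1)
  expect_equal(r$longest_dwell, 4)  # 4 frames at unit spacing
  s_alt <- data.frame(time = 1:6, value = rep(c(0.1, 0.9), 3))
  r2 <- residence(s_alt, cutoff = 0.5)
  expect_equal(r2$fraction_within, 0.5)
  expect_equal(r2$n_entries, 3L)
  s_none <- data.frame(time = 1:3, value = c(2, 3, 2))
  r3 <- residence(s_none, cutoff = 0.5)
  expect_equal(r3$fraction_within, 0)
  expect_equal(r3$n_entries, 0L)
  expect_equal(r3$longest_dwell, 0)
  expect_error(residence(s_all, cutoff = 0), "cutoff")
})

test_that("residence of a concatenation is the frame-weighted mean of parts", {
  set.seed(2)
  v1 <- runif(40); v2 <- runif(60)
  r1 <- residence(data.frame(time = 1:40, value = v1), 0.5)
  r2 <- residence(data.frame(time = 1:60, value = v2), 0.5)
  rc <- residence(data.frame(time = 1:100, value = c(v1, v2)), 0.5)
  expect_equal(rc$fraction_within,
               (40 * r1$fraction_within + 60 * r2$fraction_within) / 100)
})

test_that("Kabsch superposition recovers rigid motions and matches a search oracle", {
  set.seed(3)
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(superpose_rmsd(a, a)$rmsd, 0)
  # rigidly moved copy superposes exactly
  ax <- c(1, 2, 2) / 3; th <- 1.1
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  b <- a %*% t(R) + matrix(c(1, -2, 0.5), 5, 3, byrow = TRUE)
  sp <- superpose_rmsd(a, b)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  # symmetry
  p <- matrix(rnorm(9), 3, 3)
  q <- p + 0.1 * matrix(rnorm(9), 3, 3)
  expect_equal(superpose_rmsd(p, q)$rmsd, superpose_rmsd(q, p)$rmsd,
               tolerance = 1e-9)
  # independent oracle: direct minimization of RMSD over rotations
  # (axis-angle parameterization, multi-start Nelder-Mead), no Kabsch
  rot <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    ax <- v / th
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  obj <- function(v) sqrt(mean(rowSums((qc %*% t(rot(v)) - pc)^2)))
  set.seed(4)
  best <- Inf
  for (i in 1:40) {
    o <- optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
    best <- min(best, o$value)
  }
  expect_equal(superpose_rmsd(p, q)$rmsd, best, tolerance = 1e-3)
  # applying the optimal superposition then re-superposing changes nothing
  q_fit <- q %*% t(sp$rotation)
  sp2 <- superpose_rmsd(p, q)
  q_fit <- sweep(q %*% t(sp2$rotation), 2, as.numeric(sp2$translation), `+`)
  expect_equal(superpose_rmsd(p, q_fit)$rmsd, sp2$rmsd, tolerance = 1e-9)
  expect_error(superpose_rmsd(p, p[1:2, ]), "mismatched")
})

test_that("frame energies reproduce the analytic potential", {
  spec <- funnel_landscape_spec(start_position = c(8, 0))
  fld <- gen_landscape(spec)
  pinned <- sumdkin:::new_trajectory(times = 1:5,
                                     coords = matrix(0, 5, 2),
                                     stride = 1, timestep = 1)
  expect_equal(frame_energy(pinned, fld)$energy, rep(-8, 5))
  far <- sumdkin:::new_trajectory(times = 1:3,
                                  coords = cbind(c(6, 7, 8), 0),
                                  stride = 1, timestep = 1)
  expect_equal(frame_energy(far, fld)$energy, rep(0, 3))
  h <- harmonic_field(k = 2, center = 0, dimension = 1, box_half_width = 10)
  xs <- seq(-1, 1, by = 0.25)
  line <- sumdkin:::new_trajectory(times = seq_along(xs),
                                   coords = matrix(xs, ncol = 1),
                                   stride = 1, timestep = 1)
  expect_equal(frame_energy(line, h)$energy, 0.5 * 2 * xs^2)
})

test_that("distance series evaluate supervision metrics frame by frame", {
  m <- supervision_metric("com_distance", anchors = c(0, 0))
  traj <- sumdkin:::new_trajectory(times = 1:3,
                                   coords = rbind(c(3, 4), c(0, 1), c(1, 0)),
                                   stride = 1, timestep = 1)
  ds <- distance_series(traj, m)
  expect_equal(ds$value, c(5, 1, 1))
})
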