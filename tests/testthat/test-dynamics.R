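test_that("zero temperature on a flat potential leaves the particle still", {
  fld <- flat_field(dimension = 2, box_half_width = 10)
  cfg <- integrator_config(temperature = 0, seed = 1)
  res <- advance(toy_state(c(1, -2)), fld, cfg, 500)
  expect_equal(res$state$position, c(1, -2))
})

test_that("zero-temperature harmonic relaxation matches the closed form", {
  # overdamped: x(t) = x0 exp(-k t / gamma); Euler-Maruyama bias is
  # O(n (k dt/gamma)^2), below 1e-6 at dt = 1e-5, t = 0.1
  fld <- harmonic_field(k = 1, center = 0)
  cfg <- integrator_config(timestep = 1e-5, temperature = 0)
  res <- advance(toy_state(1), fld, cfg, 10000)
  expect_equal(res$state$position, exp(-0.1), tolerance = 1e-6)
})

test_that("a split run is bit-identical to one uninterrupted run", {
  fld <- gen_landscape(m6a_funnel())
  for (mode in c("overdamped", "langevin")) {
    cfg <- integrator_config(mode = mode, seed = 99)
    s0 <- toy_state(fld$start_position)
    whole <- advance(s0, fld, cfg, 2000)
    half <- advance(s0, fld, cfg, 1000)
    rest <- advance(half$state, fld, cfg, 1000)
    expect_identical(whole$state$position, rest$state$position)
    expect_identical(whole$state$velocity, rest$state$velocity)
    expect_identical(whole$state$rng_state, rest$state$rng_state)
  }
})

test_that("free diffusion satisfies the Einstein relation", {
  cfg <- integrator_config(seed = 7)  # D = T / friction = 1
  expect_equal(msd_free(cfg, 100, 0)$msd, 0)
  m1 <- msd_free(cfg, 10000, 1, dimension = 2)
  expect_lt(abs(m1$msd - m1$expected), 3 * m1$se)
  expect_equal(m1$expected, 4)  # 2 d D t
  m2 <- msd_free(integrator_config(seed = 8), 10000, 2, dimension = 2)
  expect_lt(abs(m2$msd - 2 * m1$expected), 3 * (m2$se + 2 * m1$se))
})

test_that("long double-well sampling reproduces the Boltzmann weight", {
  dw <- double_well_field(height = 2, scale = 1, box_half_width = 4)
  cfg <- integrator_config(seed = 123, stride = 40)
  burn <- advance(toy_state(1), dw, cfg, 1000)
  run <- advance(burn$state, dw, cfg, 4e6)
  # the slow mode is barrier hopping (Kramers time ~ 4 toy-time units for a
  # 2 kT barrier); thin to 2 time units so the GOF counts are near-independent
  x <- run$trajectory$coords[seq(1, n_frames(run$trajectory), by = 50), 1]
  breaks <- c(-4, seq(-2, 2, by = 0.4), 4)
  counts <- table(cut(x, breaks))
  probs <- vapply(seq_len(length(breaks) - 1), function(i)
    integrate(function(z) exp(-vapply(z, dw$potential, numeric(1))),
              breaks[i], breaks[i + 1])$value, numeric(1))
  gof <- suppressWarnings(chisq.test(as.numeric(counts),
                                     p = probs / sum(probs)))
  expect_gt(gof$p.value, 0.01)
  # and both wells were actually visited
  expect_gt(mean(x > 0), 0.2)
  expect_gt(mean(x < 0), 0.2)
})

test_that("reflecting walls keep every frame inside the box", {
  fld <- flat_field(dimension = 2, box_half_width = 1)
  cfg <- integrator_config(temperature = 4, seed = 3)
  res <- advance(toy_state(c(0.9, 0.9)), fld, cfg, 20000)
  expect_true(all(abs(res$trajectory$coords) <= 1))
})

test_that("states outside the box or with bad shapes are rejected", {
  fld <- flat_field(dimension = 2, box_half_width = 1)
  cfg <- integrator_config(seed = 1)
  expect_error(advance(toy_state(c(5, 0)), fld, cfg, 10), "box")
  expect_error(advance(toy_state(0), fld, cfg, 10), "dimension")
})
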