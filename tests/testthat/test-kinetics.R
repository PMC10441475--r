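test_that("1:1 KD algebra reproduces the reported wild-type constants", {
  # rates as reported; KD within input-rounding of the printed values
  expect_equal(kd_one_to_one(one_to_one_params(1.64e5, 4.22e-2, 519)),
               256, tolerance = 0.01)
  expect_equal(kd_one_to_one(one_to_one_params(0.855e5, 11.6e-2, 421)),
               1360, tolerance = 0.01)
  # ratio identity: kon numerically equal to koff gives KD = 1 M
  expect_equal(kd_one_to_one(one_to_one_params(3.7, 3.7, 100)), 1e9)
})

test_that("two-state KD algebra reproduces reported mutant constants and limits", {
  expect_equal(kd_two_state(two_state_params(2.59e4, 2.17e-2, 6.02e-3,
                                             4.54e-4, 697)),
               58.8, tolerance = 0.005)
  expect_equal(kd_two_state(two_state_params(5.38e3, 4.00e-2, 2.14e-3,
                                             8.79e-4, 552)),
               2160, tolerance = 0.005)
  # no second state: reduces to the binding-step KD
  p <- two_state_params(1e5, 1e-2, 0, 1e-3, 500)
  expect_equal(kd_two_state(p), kd_one_to_one(one_to_one_params(1e5, 1e-2, 500)))
})

test_that("two-state KD is monotone in each rate constant", {
  set.seed(10)
  for (i in 1:20) {
    p <- random_two_state()
    up <- function(f, v) {q <- unclass(p); q[[f]] <- q[[f]] * v
      do.call(two_state_params, q)}
    expect_gt(kd_two_state(up("koff1", 2)), kd_two_state(p))
    expect_gt(kd_two_state(up("koff2", 2)), kd_two_state(p))
    expect_lt(kd_two_state(up("kon1", 2)), kd_two_state(p))
    expect_lt(kd_two_state(up("kon2", 2)), kd_two_state(p))
  }
})

test_that("1:1 simulation matches its closed-form limits", {
  p <- one_to_one_params(1e5, 1e-2, 500)
  # no analyte, no response
  z <- injection_schedule(0, association_s = 100,
                          inter_dissociation_s = 0,
                          final_dissociation_s = 0, sample_rate = 1)
  expect_true(all(simulate_one_to_one(p, z)$data$response_RU == 0))
  # long association approaches the Langmuir isotherm
  C <- 2e-7
  long <- injection_schedule(C, association_s = 5000,
                             inter_dissociation_s = 0,
                             final_dissociation_s = 0, sample_rate = 0.01)
  plateau <- tail(simulate_one_to_one(p, long)$data$response_RU, 1)
  expect_equal(plateau, 500 * C / (C + 1e-2 / 1e5), tolerance = 1e-6)
  # dissociation from R0 is a pure exponential, checked at t = 1/koff
  p2 <- one_to_one_params(1e5, 1e-2, 500)
  sch <- injection_schedule(1e-6, association_s = 5000,
                            inter_dissociation_s = 0,
                            final_dissociation_s = 200, sample_rate = 0.01)
  sg <- simulate_one_to_one(p2, sch)
  R0 <- sg$data$response_RU[sg$data$time_s == 5000]
  R_at <- sg$data$response_RU[sg$data$time_s == 5100]
  expect_equal(R_at, R0 * exp(-1e-2 * 100), tolerance = 1e-9)
})

test_that("two-state simulation is consistent with its equilibrium algebra", {
  set.seed(20)
  for (i in 1:20) {
    p <- random_two_state()
    kd_M <- kd_two_state(p) * 1e-9
    C <- kd_M * runif(1, 0.5, 5)
    # run long enough to damp the slowest relaxation mode of the 2x2
    # rate matrix (independent eigenvalue computation)
    A <- rbind(c(-(p$kon1 * C + p$koff1 + p$kon2), p$koff2 - p$kon1 * C),
               c(p$kon2, -p$koff2))
    t_eq <- 30 / min(abs(Re(eigen(A)$values)))
    sch <- injection_schedule(C, association_s = t_eq,
                              inter_dissociation_s = 0,
                              final_dissociation_s = 0,
                              sample_rate = 10 / t_eq)
    sg <- simulate_two_state(p, sch)
    plateau <- tail(sg$data$response_RU, 1)
    expect_equal(plateau, p$Rmax * C / (C + kd_M), tolerance = 1e-3)
    # conservation of binding sites in every frame
    comp <- sg$metadata$components
    expect_true(all(comp >= -1e-9))
    expect_true(all(rowSums(comp) <= p$Rmax + 1e-9))
  }
})

test_that("two-state with kon2 = 0 reproduces the 1:1 trace everywhere", {
  sch <- fast_schedule()
  s1 <- simulate_one_to_one(one_to_one_params(1e5, 1e-2, 500), sch)
  s2 <- simulate_two_state(two_state_params(1e5, 1e-2, 0, 1e-3, 500), sch)
  expect_lt(max(abs(s1$data$response_RU - s2$data$response_RU)), 1e-8)
})

test_that("the analytic propagator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- reference_two_state_params("rNEAT2", "R298P")
  sch <- fast_schedule()
  sg <- simulate_two_state(p, sch)
  rhs <- function(t, x, parms) {
    C <- sumdkin:::conc_at_times(sch, t)
    list(c(p$kon1 * C * (p$Rmax - x[1] - x[2]) - p$koff1 * x[1] -
             p$kon2 * x[1] + p$koff2 * x[2],
           p$kon2 * x[1] - p$koff2 * x[2]))
  }
  times <- c(0, sg$data$time_s)
  o <- deSolve::ode(c(0, 0), times, rhs, NULL, rtol = 1e-10, atol = 1e-10,
                    method = "lsoda")
  ref <- rowSums(o[-1, 2:3, drop = FALSE])
  expect_lt(max(abs(ref - sg$data$response_RU)), 1e-5 * p$Rmax)
})

test_that("noiseless sensorgram fits recover the generating parameters", {
  # 1:1 over the standard single-cycle schedule
  truth <- one_to_one_params(1e5, 1e-2, 500)
  f <- fit_sensorgram(simulate_one_to_one(truth, fast_schedule()),
                      "one_to_one", n_starts = 4, seed = 1)
  expect_true(f$converged)
  for (nm in c("kon", "koff", "Rmax"))
    expect_equal(f$params[[nm]], truth[[nm]], tolerance = 1e-4)
  # two-state: KD recovered within 1 %
  p <- reference_two_state_params("rNEAT2", "R298P")  # Rmax 373
  f2 <- fit_sensorgram(simulate_two_state(p, fast_schedule()),
                       "two_state", n_starts = 8, seed = 1)
  expect_true(f2$converged)
  expect_equal(f2$derived_kd_nM, kd_two_state(p), tolerance = 0.01)
  # fitting the wrong (nested) model to a strongly two-state trace loses
  sg2 <- simulate_two_state(p, fast_schedule())
  f_wrong <- fit_sensorgram(sg2, "one_to_one", n_starts = 4, seed = 1)
  expect_gt(f_wrong$residual_sse, f2$residual_sse)
})

test_that("fold changes round the way affinity claims are quoted", {
  expect_equal(fold_change(1360, 256, sig_digits = NULL), 5.3125)
  expect_equal(round(fold_change(1360, 256, sig_digits = NULL)), 5)
  expect_equal(fold_change(11.6e-2, 4.22e-2), 2.7)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(2, 8, sig_digits = NULL), 4)  # order-free
  expect_error(fold_change(-1, 2), "a > 0")
})

test_that("parameter constructors enforce positivity", {
  expect_error(one_to_one_params(-1, 1, 1))
  expect_error(two_state_params(1, 1, -1, 1, 1))
  expect_error(injection_schedule(c(2, 1) * 1e-9), "non-decreasing")
})
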