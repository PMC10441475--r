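test_that("fit_slope reproduces exact lines and the normal equations", {
  expect_equal(fit_slope(cbind(0:2, c(3, 2, 1))), -1)
  expect_equal(fit_slope(cbind(0:2, c(2, 2, 2))), 0)
  t <- 0:3; d <- c(1.0, 1.4, 1.1, 1.9)
  oracle <- sum((t - mean(t)) * (d - mean(d))) / sum((t - mean(t))^2)
  expect_equal(fit_slope(list(time = t, distance = d)), oracle,
               tolerance = 1e-12)
  expect_error(fit_slope(cbind(1, 2)), "at least 2")
  expect_error(fit_slope(cbind(c(1, 1, 1), c(1, 2, 3))), "degenerate")
})

test_that("supervised windows follow the slope rule and replay deterministically", {
  fld <- gen_landscape(funnel_landscape_spec(start_position = c(3, 0)))
  metric <- supervision_metric("com_distance", anchors = c(0, 0))
  # deterministic drift toward the well: negative slope, accept
  cfg0 <- integrator_config(temperature = 0)
  w <- supervise_window(toy_state(c(3, 0)), fld, cfg0, metric, 0.2)
  expect_lt(w$slope, 0)
  expect_identical(w$decision, "accept")
  # fixed RNG token: identical samples, slope, decision
  cfg <- integrator_config(seed = 5)
  set.seed(5); s0 <- toy_state(c(3, 0), rng_state = sumdkin:::get_rng_token())
  w1 <- supervise_window(s0, fld, cfg, metric, 0.2)
  w2 <- supervise_window(s0, fld, cfg, metric, 0.2)
  expect_identical(w1$samples, w2$samples)
  expect_identical(w1$slope, w2$slope)
  expect_identical(w1$decision, w2$decision)
  # decision is sign(slope) < 0 with no override
  expect_identical(w1$decision, if (w1$slope < 0) "accept" else "reject")
})

test_that("an already-satisfied threshold binds with zero windows", {
  spec <- m6a_funnel()
  fld <- gen_landscape(spec)
  plan <- list(list(metric = supervision_metric("com_distance",
                                                anchors = spec$well_center),
                    threshold = 9))  # start is at distance 8
  res <- run_sumd(toy_system(fld), supervision_config(plan, seed = 1))
  expect_identical(res$outcome, "bound")
  expect_identical(res$n_windows, 0L)
  expect_identical(res$first_passage_time, 0)
})

test_that("deterministic descent accepts every window and binds", {
  spec <- funnel_landscape_spec(start_position = c(3, 0))
  fld <- gen_landscape(spec)
  res <- run_sumd(toy_system(fld),
                  supervision_config(default_stage_plan(spec), seed = 1),
                  integrator_config(temperature = 0))
  expect_identical(res$outcome, "bound")
  expect_true(all(res$log$decision == "accept"))
  expect_equal(res$simulated_time, nrow(res$log) * 0.2)
  expect_identical(res$discarded_time, 0)
})

test_that("every logged supervised window obeys decision == (slope < 0)", {
  spec <- m6a_funnel()
  fld <- gen_landscape(spec)
  res <- run_sumd(toy_system(fld),
                  supervision_config(default_stage_plan(spec), seed = 42,
                                     max_total_windows = 2000))
  log <- res$log
  sup <- log[log$decision != "escape", ]
  expect_gt(nrow(sup), 10)
  expect_identical(sup$decision == "accept", sup$slope < 0)
  esc <- log[log$decision == "escape", ]
  expect_true(all(is.na(esc$slope)))
})

test_that("accepted states chain contiguously within a stage", {
  spec <- m6a_funnel()
  fld <- gen_landscape(spec)
  res <- run_sumd(toy_system(fld),
                  supervision_config(default_stage_plan(spec), seed = 7,
                                     max_total_windows = 2000))
  log <- res$log
  for (i in seq_len(nrow(log) - 1)) {
    if (log$stage[i] != log$stage[i + 1]) next
    ref <- if (log$decision[i] %in% c("accept", "escape"))
      log$metric_end[i] else log$metric_start[i]
    expect_identical(log$metric_start[i + 1], ref)
  }
})

test_that("the escape rule fires after the configured failure run", {
  # a barrier ring makes rejections frequent enough to trigger escapes
  spec <- funnel_landscape_spec(start_position = c(6, 0), barrier_height = 6,
                                well_depth = 8)
  fld <- gen_landscape(spec)
  cfg <- supervision_config(default_stage_plan(spec), seed = 11,
                            max_consecutive_failures = 3,
                            escape_multiplier = 5, max_total_windows = 400)
  res <- run_sumd(toy_system(fld), cfg)
  log <- res$log
  esc <- which(log$decision == "escape")
  expect_gt(length(esc), 0)
  for (e in esc) {
    prior <- log$decision[seq_len(e - 1)]
    run_len <- rle(rev(prior))$lengths[1]
    expect_identical(rev(prior)[1], "reject")
    expect_gte(run_len, 3)
  }
})

test_that("swarms select the first bound replicas reproducibly", {
  spec <- funnel_landscape_spec(start_position = c(3, 0))
  fld <- gen_landscape(spec)
  sys <- toy_system(fld)
  plan <- default_stage_plan(spec)
  # deterministic descent: all replicas bind
  sw <- run_swarm(sys, supervision_config(plan, seed = 1), 3, 3,
                  integrator_config(temperature = 0))
  expect_identical(sw$n_bound, 3L)
  expect_length(sw$selected, 3)
  # selection is reproducible and takes the lowest bound indices
  cfg <- supervision_config(plan, seed = 10, max_total_windows = 500)
  sw1 <- run_swarm(sys, cfg, 8, 3)
  sw2 <- run_swarm(sys, cfg, 8, 3)
  expect_identical(names(sw1$selected), names(sw2$selected))
  bound_idx <- which(sw1$outcomes == "bound")
  expect_identical(as.integer(names(sw1$selected)),
                   bound_idx[seq_len(min(3, length(bound_idx)))])
  # too few bound replicas warns and returns what bound
  hard <- funnel_landscape_spec(start_position = c(9.5, 0), well_depth = 2)
  cfg_hard <- supervision_config(default_stage_plan(hard), seed = 2,
                                 max_total_windows = 5)
  expect_warning(swh <- run_swarm(toy_system(gen_landscape(hard)),
                                  cfg_hard, 3, 3),
                 "replicas bound")
  expect_lte(length(swh$selected), 3)
})

test_that("metric evaluation matches hand geometry", {
  m <- supervision_metric("com_distance", anchors = rbind(c(0, 0), c(2, 0)),
                          masses = c(1, 3))
  expect_equal(eval_metric(m, c(10, 0)), 8.5)  # centroid at x = 1.5
  mp <- supervision_metric("pair_distance_set",
                           anchors = rbind(c(0, 0), c(2, 0)),
                           combine = "mean")
  expect_equal(eval_metric(mp, c(10, 0)), (10 + 8) / 2)
  mx <- supervision_metric("pair_distance_set",
                           anchors = rbind(c(0, 0), c(2, 0)), combine = "max")
  expect_equal(eval_metric(mx, c(10, 0)), 10)
})
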