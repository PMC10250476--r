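test_that("zero-noise standing renders the static template", {
  cfg <- sim_config(noise_sd = 0, look_around_amp = 0, seed = 3)
  sim <- generate_track(data.frame(behavior = "standing", duration = 50), cfg)
  expect_equal(n_frames(sim$track), 50L)
  # all frames identical
  expect_equal(max(apply(sim$track$x, 2, function(v) diff(range(v)))), 0)
  expect_equal(max(apply(sim$track$y, 2, function(v) diff(range(v)))), 0)
  # and equal to the template placed at the canvas center
  expect_equal(unname(sim$track$x[1, ]),
               unname(cfg$template[, "x"] + cfg$canvas[1] / 2))
  expect_equal(unname(sim$track$y[1, ]),
               unname(cfg$template[, "y"] + cfg$canvas[2] / 2))
})

test_that("generation is bit-identical under a fixed seed", {
  script <- data.frame(behavior = c("walking", "head_shake", "preening"),
                       duration = c(40, 30, 50))
  a <- generate_track(script, sim_config(seed = 9))
  b <- generate_track(script, sim_config(seed = 9))
  expect_identical(a$track$x, b$track$x)
  expect_identical(a$track$y, b$track$y)
  expect_identical(a$track$likelihood, b$track$likelihood)
  c_ <- generate_track(script, sim_config(seed = 10))
  expect_false(identical(a$track$x, c_$track$x))
})

test_that("label slices exactly tile the generated track", {
  script <- data.frame(behavior = sim_behaviors(), duration = 200)
  sim <- generate_track(script, sim_config(seed = 2))
  expect_equal(n_frames(sim$track), 1400L)
  expect_equal(nrow(sim$labels), 7L)
  expect_equal(sim$labels$start_frame, seq(0L, 1200L, by = 200L))
  expect_equal(sim$labels$end_frame, seq(199L, 1399L, by = 200L))
  lf <- apply_labels(sim$labels, sim$track)
  expect_true(all(lf$class_counts == 200L))
  expect_error(generate_track(data.frame(behavior = "flying", duration = 10),
                              sim_config()), "unknown behavior")
})

test_that("the beak is occluded often enough to fail feature selection", {
  sim <- small_sim()
  lik <- sim$track$likelihood
  beak <- lik[, "beak"]
  expect_lt(mean(beak), 0.6)
  expect_true(any(beak < 0.5))
  expect_true(all(lik[, colnames(lik) != "beak"] >= 0.9))
})

test_that("the benchmark is skewed, valid and covers all behaviors", {
  bench <- make_benchmark(8000, config = sim_config(seed = 4))
  shares <- prop.table(tapply(
    bench$labels$end_frame - bench$labels$start_frame + 1L,
    bench$labels$behavior, sum))
  expect_setequal(names(shares), sim_behaviors())
  expect_lt(shares[["head_shake"]], 0.05)
  expect_lt(shares[["tail_shake"]], 0.05)
  expect_gt(shares[["standing"]], shares[["head_shake"]])
  expect_true(validate_labels(bench$labels, bench$track)$valid)
  expect_equal(sum(bench$script$duration), n_frames(bench$track))
  zero <- default_imbalance_profile()
  zero["eating"] <- 0
  expect_error(make_benchmark(1000, profile = zero), "positive")
})

test_that("normalization flattens walking into a constant posture", {
  cfg <- sim_config(noise_sd = 0, look_around_amp = 0, seed = 5,
                    random_placement = TRUE)
  sim <- generate_track(data.frame(behavior = "walking", duration = 80), cfg)
  # raw coordinates drift (global translation)...
  drift <- sqrt((sim$track$x[80, "body"] - sim$track$x[1, "body"])^2 +
                (sim$track$y[80, "body"] - sim$track$y[1, "body"])^2)
  expect_gt(drift, 200)
  # ...but the egocentric posture is constant
  nt <- normalize_track(sim$track)
  expect_lt(max(apply(nt$track$x, 2, function(v) diff(range(v)))), 1e-6)
  expect_lt(max(apply(nt$track$y, 2, function(v) diff(range(v)))), 1e-6)
})
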