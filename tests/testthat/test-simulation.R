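test_that("session plans reproduce the design composition for any seed", {
  for (seed in c(1, 99, 12345)) {
    plan <- build_experiment("letter", n_sessions = 25, seed = seed)
    expect_equal(nrow(plan), 25 * 48)
    expect_equal(sum(plan$trial_type == "test"), 300)
    counts <- table(plan$session, plan$trial_type)
    expect_true(all(counts[, "baseline_easy"] == 12))
    expect_true(all(counts[, "baseline_difficult"] == 24))
    expect_true(all(counts[, "test"] == 12))
    # unique noise ids across the whole experiment
    ids <- c(plan$stim_id_1, plan$stim_id_2, plan$stim_id_3)
    expect_equal(anyDuplicated(ids), 0)
    # grid cells distinct within a trial; test trials have no correct slot
    cells <- plan[, c("cell_1", "cell_2", "cell_3")]
    expect_true(all(apply(cells, 1, function(r) length(unique(r)) == 3)))
    expect_true(all(is.na(plan$correct_slot[plan$trial_type == "test"])))
    expect_true(all(!is.na(plan$correct_slot[plan$trial_type != "test"])))
  }
  expect_identical(build_experiment("letter", 2, seed = 4),
                   build_experiment("letter", 2, seed = 4))
})

test_that("grid cells are counterbalanced across trials", {
  plan <- build_experiment("letter", n_sessions = 25, seed = 11)
  used <- table(factor(c(plan$cell_1, plan$cell_2, plan$cell_3),
                       levels = 0:5))
  # each cell appears in half the trials; Binomial(1200, 0.5) puts
  # counts within +/- 5 sd = 87 of 600
  expect_true(all(abs(used - 600) < 87))
})

test_that("a zero-beta observer chooses uniformly", {
  geom <- tiny_geom()
  set.seed(21)
  stim <- lapply(1:3, function(i)
    generate_noise(geom$canvas_w, geom$canvas_h)$pixels)
  tpl <- generate_noise(geom$target_w, geom$target_h)$pixels
  obs <- observer(tpl + 0, beta = 0, lapse = 0, rt_sd = 0)
  plan <- data.frame(trial_type = "test", cell_1 = 0L, cell_2 = 1L,
                     cell_3 = 2L)
  draws <- replicate(6000, simulate_choice(stim, plan, obs,
                                           default_aoi(geom))$chosen_slot)
  gof <- chisq.test(table(factor(draws, levels = 1:3)))
  expect_gt(gof$p.value, 0.01)
})

test_that("a sharp template observer nails easy baselines and slows on test trials", {
  fx <- tiny_fx()  # beta = 50, lapse = 0
  log <- fx$log
  easy <- log[log$trial_type == "baseline_easy", ]
  expect_gt(mean(easy$correct), 0.99)
  # evidence-dependent RTs: target-absent trials are slower than easy
  # baselines (the qualitative mean-RT ordering of the task)
  expect_gt(mean(log$rt_ms[log$trial_type == "test"]),
            mean(easy$rt_ms))
  expect_true(all(log$rt_ms > 0))
})

test_that("the correction procedure books exactly one flagged trial per error", {
  fx <- tiny_fx()
  log <- fx$log
  base <- log[log$trial_type %in% c("baseline_easy", "baseline_difficult"), ]
  expect_equal(sum(log$is_correction), sum(!base$correct))
  expect_true(all(log$trial_type[log$is_correction] == "correction"))
  expect_true(all(log$correct[log$is_correction]))
  # corrections never enter the choice dataset
  expect_equal(n_trials(build_choice_dataset(log, fx$store, fx$aoi)),
               sum(log$trial_type == "test"))
  # a lapsing observer generates errors and therefore corrections
  lapser <- observer(fx$template, beta = 0, lapse = 1, rt_sd = 0)
  plan <- build_experiment("human_face", 2, seed = 31,
                           composition = c(easy = 6, difficult = 6,
                                           test = 2))
  res <- run_experiment(plan, lapser, geometry = fx$geometry, seed = 32,
                        store = NULL)
  n_err <- sum(!res$log$correct[!res$log$is_correction &
                                  res$log$trial_type != "test"])
  expect_gt(n_err, 0)
  expect_equal(sum(res$log$is_correction), n_err)
  expect_equal(nrow(res$log), nrow(plan) + n_err)
})

test_that("test-trial reward is a fair coin regardless of policy", {
  fx <- tiny_fx()
  rewarded <- fx$log$rewarded[fx$log$trial_type == "test"]
  n <- length(rewarded)
  expect_equal(n, 1200)
  # 99% binomial CI at n = 1200: 0.5 +/- 2.576 * sqrt(0.25 / n)
  expect_lt(abs(mean(rewarded) - 0.5), 2.576 * sqrt(0.25 / n))
})

test_that("runs are reproducible under a fixed seed", {
  plan <- build_experiment("letter", 1, seed = 8,
                           composition = c(easy = 2, difficult = 2,
                                           test = 2))
  geom <- tiny_geom()
  bank <- make_target_bank("letter", 20, seed = 9,
                           width = geom$target_w, height = geom$target_h)
  obs <- observer(bank_mean(bank))
  r1 <- run_experiment(plan, obs, geometry = geom, seed = 77,
                       target_bank = bank)
  r2 <- run_experiment(plan, obs, geometry = geom, seed = 77,
                       target_bank = bank)
  expect_identical(r1$log, r2$log)
  ids <- ls(r1$store)
  expect_identical(mget(ids, envir = r1$store), mget(ids, envir = r2$store))
})

test_that("observer parameters are validated", {
  tpl <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_error(observer(matrix(5, 3, 3)), "zero variance")
  expect_error(observer(tpl, beta = -1), "beta")
  expect_error(observer(tpl, lapse = 1.2), "lapse")
  expect_error(observer(tpl, position_bias = 1:3), "position_bias")
})
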