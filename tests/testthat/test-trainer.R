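# Schedule, objective and stage-contract tests; training smoke tests run
# at deliberately small problem sizes.

small_data <- function(n, C = 12, hw = 8, seed = 1,
                       informative = c(1, 4, 8), noise = 0.005) {
  cfg <- phantom_config(n_bands = C, height = hw + 2, width = hw + 2,
                        informative_bands = informative, noise_sd = noise,
                        n_samples = n, seed = seed)
  ds <- generate_dataset(cfg)
  hsiband:::patches_from_samples(ds$samples, ds$manifest$ssc, hw)
}

test_that("loss-weight schedules move focus from reconstruction to regression", {
  se <- c(4L, 3L, 1L)
  w0 <- schedule_weights(0, 8, se)
  expect_equal(w0$alpha, 1.0); expect_equal(w0$beta, 0.1)
  wl <- schedule_weights(6, 8, se)              # last Stage-1 epoch
  expect_equal(wl$alpha, 0.1); expect_equal(wl$beta, 1.0)
  w2 <- schedule_weights(7, 8, se)              # Stage 2
  expect_equal(w2$alpha, 0.1); expect_equal(w2$beta, 1.0)
  ## the symmetric linear schedules sum to 1.1 throughout Stages 0-1
  for (e in 0:6)
    expect_equal(with(schedule_weights(e, 8, se), alpha + beta), 1.1)
  ## alpha nonincreasing, beta nondecreasing over the whole run
  al <- vapply(0:7, function(e) schedule_weights(e, 8, se)$alpha, 1)
  be <- vapply(0:7, function(e) schedule_weights(e, 8, se)$beta, 1)
  expect_true(all(diff(al) <= 1e-12))
  expect_true(all(diff(be) >= -1e-12))
  expect_error(schedule_weights(8, 8, se), "epoch")
})

test_that("the joint objective is the stated weighted sum", {
  w <- list(alpha = 0.5, beta = 0.5, lambda = 0.01)
  expect_equal(total_loss(0, 0, 0, w), 0)
  expect_equal(total_loss(1, 1, 1, w), 1.01)
  expect_equal(total_loss(1, 2, 1, w) - total_loss(1, 1, 1, w), 0.5)
  expect_error(total_loss(-1, 0, 0, w), "negative")
})

test_that("the adaptive threshold solves the pass-count equation", {
  for (seed in 1:5) {
    a <- hsiband:::with_seed(seed, runif(24))
    tau <- hsiband:::solve_tau(a, K = 6, T_pass = 0.1)
    expect_equal(soft_pass_count(a, tau, 0.1), 6, tolerance = 1e-4)
  }
})

test_that("stage freezing and fixation contracts hold", {
  dat <- small_data(12, seed = 21)
  plan <- stage_plan(total_epochs = 4L, stage_epochs = c(2L, 1L, 1L),
                    batch_size = 4L, lr = 1e-2, augment = FALSE)
  model <- hsi_model(12, K = 4, base_width = 4, hidden = 4, seed = 1)
  model$state$next_stage <- 0L
  expect_error(run_stage(model, 1, dat[1:8], dat[9:12], plan),
               "stage order")
  s0 <- run_stage(model, 0, dat[1:8], dat[9:12], plan, seed = 1)
  att_before <- s0$model$params[c("att_W1", "att_b1", "att_W2", "att_b2",
                                  "att_sp_W", "att_sp_b")]
  rec_before <- s0$model$params$rec_e1_W
  s1 <- run_stage(s0$model, 1, dat[1:8], dat[9:12], plan, opt = s0$opt,
                  seed = 2)
  expect_identical(s1$model$params[names(att_before)], att_before)
  expect_false(identical(s1$model$params$rec_e1_W, rec_before))
  ## Stage 2 fixes the subset and trains only the regression head
  nonreg_before <- s1$model$params[!startsWith(names(s1$model$params),
                                               "reg_")]
  s2 <- run_stage(s1$model, 2, dat[1:8], dat[9:12], plan, opt = s1$opt,
                  seed = 3)
  expect_identical(s2$model$params[names(nonreg_before)], nonreg_before)
  expect_length(s2$model$state$hard_idx, 4L)
  expect_false(any(duplicated(s2$model$state$hard_idx)))
  ## the active set does not change across Stage-2 epochs
  expect_true(all(vapply(s2$epoch_subsets, identical,
                         TRUE, s2$model$state$hard_idx)))
})

test_that("three-stage training runs end to end and improves validation fit", {
  dat <- small_data(20, seed = 33)
  plan <- stage_plan(total_epochs = 20L, stage_epochs = c(10L, 7L, 3L),
                     batch_size = 4L, lr = 2e-2, lr_att = 5e-2,
                     augment = FALSE)
  fit <- train_joint(dat[1:16], dat[17:20], n_bands = 12, K = 4,
                     plan = plan, base_width = 4, hidden = 4, seed = 7)
  expect_length(fit$selected_bands, 4L)
  expect_equal(nrow(fit$logs), 20L)
  expect_true(all(fit$logs$stage == rep(0:2, c(10, 7, 3))))
  ## non-strict improvement over the first epoch (smoke contract)
  expect_gte(tail(fit$logs$val_r2, 1), fit$logs$val_r2[1])
  ## reproducibility under the same seed
  fit2 <- train_joint(dat[1:16], dat[17:20], n_bands = 12, K = 4,
                      plan = plan, base_width = 4, hidden = 4, seed = 7)
  expect_identical(fit$selected_bands, fit2$selected_bands)
  expect_equal(fit$logs$val_rmse, fit2$logs$val_rmse, tolerance = 1e-12)
})

test_that("a short reconstruction fit halves its training error", {
  dat <- small_data(8, seed = 5, noise = 0)
  plan <- stage_plan(total_epochs = 25L, stage_epochs = c(23L, 1L, 1L),
                     batch_size = 1L, lr = 1e-2, augment = FALSE,
                     alpha_range = c(1, 1), beta_range = c(0, 0))
  model <- hsi_model(12, K = 12, base_width = 4, hidden = 4, seed = 2)
  model$state$next_stage <- 0L
  out <- run_stage(model, 0, dat, dat[1:2], plan, seed = 3)
  expect_lt(tail(out$logs$loss_rec, 1), 0.5 * out$logs$loss_rec[1])
})

test_that("K sweeps tabulate the compactness trade-off", {
  dat <- small_data(12, seed = 41)
  plan <- stage_plan(total_epochs = 6L, stage_epochs = c(3L, 2L, 1L),
                     batch_size = 4L, lr = 1e-2, augment = FALSE)
  tab <- sweep_k(dat[1:9], dat[10:12], n_bands = 12,
                 candidate_Ks = c(3, 12), plan = plan, base_width = 4,
                 hidden = 4, seed = 2)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$K, c(3, 12))
  expect_true(all(tab$rec_mse_norm >= 0 & tab$rec_mse_norm <= 1))
  expect_error(sweep_k(dat[1:9], dat[10:12], 12, candidate_Ks = 5,
                       plan = plan), "at least 2")
})
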