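# Three-stage progressive training: exploration (all modules trained
# jointly), stabilization (attention frozen; band preferences converge and
# selection frequencies accumulate), refinement (band subset fixed by
# frequency-based top-K; only the regression head is fine-tuned).

#' Scheduled loss weights
#'
#' The reconstruction weight decreases linearly from `alpha_range[1]` to
#' `alpha_range[2]` across Stages 0-1 while the regression weight rises
#' symmetrically; both are constant during Stage 2. The band-budget weight
#' `lambda` is constant throughout.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`.
#' @param total_epochs total epoch budget.
#' @param stage_epochs length-3 epochs per stage (default 40/30/10
#'   proportions of the total).
#' @param alpha_range,beta_range start/end values of the two schedules.
#' @param lambda band-budget weight (default 0.01).
#' @return list with `alpha`, `beta`, `lambda`.
#' @export
schedule_weights <- function(epoch, total_epochs, stage_epochs = NULL,
                             alpha_range = c(1.0, 0.1),
                             beta_range = c(0.1, 1.0), lambda = 0.01) {
  if (epoch < 0 || epoch >= total_epochs)
    stopf("epoch must satisfy 0 <= epoch < total_epochs")
  stage_epochs <- stage_epochs %||% default_stage_epochs(total_epochs)
  e01 <- stage_epochs[1] + stage_epochs[2]
  if (epoch >= e01) {
    return(list(alpha = alpha_range[2], beta = beta_range[2],
                lambda = lambda))
  }
  f <- epoch / max(e01 - 1, 1)
  list(alpha = alpha_range[1] + f * (alpha_range[2] - alpha_range[1]),
       beta = beta_range[1] + f * (beta_range[2] - beta_range[1]),
       lambda = lambda)
}

default_stage_epochs <- function(total_epochs) {
  largest_remainder(total_epochs, c(40, 30, 10))
}

#' Joint training objective
#'
#' `L = alpha * L_rec + beta * L_reg + lambda * L_pass`.
#'
#' @param L_rec,L_reg,L_pass nonnegative loss components.
#' @param weights list with `alpha`, `beta`, `lambda`.
#' @return scalar total loss.
#' @export
total_loss <- function(L_rec, L_reg, L_pass, weights) {
  if (any(c(L_rec, L_reg, L_pass) < 0))
    stopf("negative loss component (metric bug upstream)")
  weights$alpha * L_rec + weights$beta * L_reg + weights$lambda * L_pass
}

#' Training plan
#'
#' @param total_epochs total epoch budget (default 80).
#' @param stage_epochs length-3 epochs per stage; default 40/30/10
#'   proportions of `total_epochs`.
#' @param batch_size minibatch size (default 8).
#' @param lr initial learning rate of the adaptive-moment optimiser
#'   (default 1e-3).
#' @param lr_att learning rate of the once-per-epoch attention update
#'   (default `lr`); the attention gradient is accumulated over the whole
#'   epoch before the step, so a larger stride is usually appropriate.
#' @param weight_decay decoupled L2 decay on multiplicative weights
#'   (default 1e-3).
#' @param input_decay additional decay on the layers that read the gated
#'   bands (first reconstruction conv, depthwise and pointwise regressor
#'   convs; default 0.05). This breaks the rescaling invariance between
#'   the per-band gate and the input weights: usefulness of a band then
#'   produces sustained upward pressure on its importance score instead of
#'   being absorbed into ever-larger weights.
#' @param lambda band-budget weight (default 0.01).
#' @param T0,T1 selection temperature annealed geometrically from `T0` to
#'   `T1` across Stages 0-1 (defaults 1.0 and 0.1).
#' @param alpha_range,beta_range endpoints of the reconstruction and
#'   regression weight schedules (see [schedule_weights()]); setting
#'   `alpha_range = c(0, 0)` trains a regression-only selector.
#' @param augment apply random flip/rotation augmentation to training
#'   patches.
#' @return list of class `stage_plan`.
#' @export
stage_plan <- function(total_epochs = 80L, stage_epochs = NULL,
                       batch_size = 8L, lr = 1e-3, lr_att = NULL,
                       weight_decay = 1e-3, input_decay = 0.05,
                       lambda = 0.01, T0 = 1.0, T1 = 0.1,
                       alpha_range = c(1.0, 0.1),
                       beta_range = c(0.1, 1.0), augment = TRUE) {
  stage_epochs <- as.integer(stage_epochs %||%
                               default_stage_epochs(total_epochs))
  if (length(stage_epochs) != 3 || any(stage_epochs < 1))
    stopf("stage_epochs must be 3 positive integers")
  structure(list(total_epochs = sum(stage_epochs),
                 stage_epochs = stage_epochs, batch_size = batch_size,
                 lr = lr, lr_att = lr_att %||% lr,
                 weight_decay = weight_decay,
                 input_decay = input_decay, lambda = lambda,
                 T0 = T0, T1 = T1, alpha_range = alpha_range,
                 beta_range = beta_range, augment = augment),
            class = "stage_plan")
}

## Exploration keeps the gate wide (constant T0 through Stage 0, so the
## regressor sees a stationary, near-open input while band utilities
## accumulate); the anneal to T1 happens across Stage 1, sharpening the
## gate around the frozen importances so the hard fixation at Stage 2 is a
## small step.
temp_at <- function(epoch, plan) {
  e0 <- plan$stage_epochs[1]
  e01 <- e0 + plan$stage_epochs[2]
  if (epoch < e0) return(plan$T0)
  if (epoch >= e01) return(plan$T1)
  f <- (epoch - e0) / max(plan$stage_epochs[2] - 1, 1)
  plan$T0 * (plan$T1 / plan$T0)^f
}

## Adaptive threshold: the tau at which the soft pass count equals the
## band budget K. K~(tau) is strictly decreasing, so the root is unique;
## it is bracketed by the importance range widened by a few counting
## temperatures.
solve_tau <- function(a, K, T_pass) {
  C <- length(a)
  lo <- min(a) - 20 * T_pass
  hi <- max(a) + 20 * T_pass
  ## a full (or overfull) budget has no interior root: every band passes
  if (K >= soft_pass_count(a, lo, T_pass)) return(lo)
  if (K <= soft_pass_count(a, hi, T_pass)) return(hi)
  stats::uniroot(function(tau) soft_pass_count(a, tau, T_pass) - K,
                 c(lo, hi), tol = 1e-8)$root
}

## Random flips / 90-degree rotation on an (H, W, C) patch.
augment_hwc <- function(x, seed) {
  f <- with_seed(seed, stats::runif(3) < 0.5)
  if (f[1]) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  if (f[2]) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  if (f[3] && dim(x)[1] == dim(x)[2])
    x <- aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
  x
}

#' Run one training stage
#'
#' Stage 0 trains all modules jointly; Stage 1 freezes the attention
#' parameters; Stage 2 first fixes the deployable band subset by
#' frequency-based top-K (replacing the soft gate with a hard mask) and
#' then updates only the regression head. The adaptive threshold tracks the
#' `(1 - K/C)` quantile of the importance vector by an exponential moving
#' average (momentum 0.9) on training passes, and selection frequencies are
#' counted on both training and validation passes while the selector is
#' soft. The best-validation-RMSE parameters of the stage are restored at
#' its end.
#'
#' @param model an [hsi_model()].
#' @param stage_id 0, 1 or 2; stages must be run in order.
#' @param train_data,val_data lists of `list(x = (H,W,C) array in [0,1],
#'   y = label)`.
#' @param plan a [stage_plan()].
#' @param opt optimiser state from the previous stage, or `NULL`.
#' @param seed integer seed (shuffling, augmentation).
#' @return list with updated `model`, `opt`, `logs` (one row per epoch) and
#'   `epoch_subsets` (top-K subset after each epoch).
#' @export
run_stage <- function(model, stage_id, train_data, val_data, plan,
                      opt = NULL, seed = 1L) {
  stopifnot(inherits(model, "hsi_model"), inherits(plan, "stage_plan"))
  expected <- model$state$next_stage %||% 0L
  if (stage_id != expected)
    stopf("stage order violation: expected stage %d, got %d", expected,
          stage_id)
  cfg <- model$config
  C <- cfg$n_bands
  if (is.null(opt)) opt <- adam_init(model$params)
  offset <- if (stage_id == 0L) 0L else sum(plan$stage_epochs[seq_len(stage_id)])
  n_ep <- plan$stage_epochs[stage_id + 1L]
  trainable <- trainable_for_stage(model$params, stage_id)

  hard_gate <- NULL
  if (stage_id == 2L) {
    if (is.null(model$state$hard_idx)) {
      sel <- model$state$sel
      a_mean <- if (sel$a_n > 0) sel$a_sum / sel$a_n else NULL
      model$state$hard_idx <- finalize_topk(sel$freq, cfg$K, a_mean = a_mean)
    }
    hard_gate <- as.numeric((seq_len(C) - 1L) %in% model$state$hard_idx)
  }
  soft <- is.null(hard_gate)
  need_recon <- stage_id < 2L

  n_train <- length(train_data)
  logs <- vector("list", n_ep)
  epoch_subsets <- vector("list", n_ep)
  best_rmse <- Inf
  best_params <- model$params

  ## Attention parameters are updated once per epoch from the epoch-mean
  ## gradient: the per-sample band-utility gradient has a small mean and
  ## a large residual-driven variance, so per-batch adaptive steps reduce
  ## to a random walk, while the epoch aggregate has a stable direction.
  att_names <- trainable[startsWith(trainable, "att_")]
  batch_names <- setdiff(trainable, att_names)

  for (le in seq_len(n_ep) - 1L) {
    ge <- offset + le
    wts <- schedule_weights(ge, plan$total_epochs, plan$stage_epochs,
                            alpha_range = plan$alpha_range %||% c(1.0, 0.1),
                            beta_range = plan$beta_range %||% c(0.1, 1.0),
                            lambda = plan$lambda)
    Temp <- temp_at(ge, plan)
    ord <- with_seed((seed + 977L * ge) %% 2147483647,
                     sample.int(n_train))
    sums <- c(total = 0, rec = 0, reg = 0, pass = 0)
    att_acc <- list()
    for (bs in split(ord, ceiling(seq_along(ord) / plan$batch_size))) {
      gacc <- list()
      for (i in bs) {
        x <- train_data[[i]]$x
        if (plan$augment)
          x <- augment_hwc(x, (seed + 613L * ge + 7L * i) %% 2147483647)
        res <- joint_loss_grads(model, x, train_data[[i]]$y, wts, Temp,
                                hard_gate = hard_gate,
                                need_recon = need_recon && wts$alpha > 0)
        if (soft) {
          qt <- solve_tau(res$a, cfg$K, cfg$T_pass)
          model$state$tau <- 0.9 * model$state$tau + 0.1 * qt
          model$state$sel <- update_frequencies(model$state$sel, res$a,
                                                model$state$tau)
        }
        sums <- sums + c(res$total, res$L_rec, res$L_reg, res$L_pass)
        gacc <- grad_add(gacc, res$grads)
      }
      gm <- grad_scale(gacc, 1 / length(bs))
      gn <- sqrt(sum(vapply(gm, function(g) sum(g * g), 1)))
      if (is.na(gn)) next                   # skip a blown-up batch
      if (gn > 5) gm <- grad_scale(gm, 5 / gn)
      att_acc <- grad_add(att_acc, gm[intersect(names(gm), att_names)])
      st <- adam_step(model$params, gm, opt, lr = plan$lr,
                      trainable = batch_names,
                      weight_decay = plan$weight_decay %||% 0,
                      decay = grep("_(W|W1|W2|k|w)$", names(model$params),
                                   value = TRUE),
                      input_decay = plan$input_decay %||% 0,
                      input_layers = c("rec_e1_W", "reg_dw_k", "reg_pw_W"))
      model$params <- st$params
      opt <- st$state
    }

    if (length(att_names) > 0 && length(att_acc) > 0) {
      n_batches <- ceiling(n_train / plan$batch_size)
      st <- adam_step(model$params, grad_scale(att_acc, 1 / n_batches),
                      opt, lr = plan$lr_att %||% plan$lr,
                      trainable = att_names,
                      weight_decay = plan$weight_decay %||% 0,
                      decay = grep("_(W|W1|W2|k|w)$", names(model$params),
                                   value = TRUE))
      model$params <- st$params
      opt <- st$state
    }

    ## validation pass (frequencies also counted while the selector is soft)
    yv <- vapply(val_data, function(s) s$y, 1)
    yhat <- numeric(length(val_data))
    for (j in seq_along(val_data)) {
      fw <- net_forward(model$params, val_data[[j]]$x, model$state$tau,
                        Temp, hard_gate = hard_gate, need_recon = FALSE,
                        Kbud = cfg$K)
      yhat[j] <- fw$yhat
      if (soft)
        model$state$sel <- update_frequencies(model$state$sel, fw$a,
                                              model$state$tau)
    }
    val_rmse <- sqrt(mean((yhat - yv)^2))
    val_r2 <- if (length(yv) >= 2 && stats::var(yv) > 0)
      1 - sum((yv - yhat)^2) / sum((yv - mean(yv))^2) else NA_real_

    epoch_subsets[[le + 1L]] <- if (soft) {
      sel <- model$state$sel
      finalize_topk(sel$freq, cfg$K,
                    a_mean = if (sel$a_n > 0) sel$a_sum / sel$a_n else NULL)
    } else model$state$hard_idx

    if (val_rmse < best_rmse) {
      best_rmse <- val_rmse
      best_params <- model$params
    }
    logs[[le + 1L]] <- data.frame(
      stage = stage_id, epoch = ge, alpha = wts$alpha, beta = wts$beta,
      lambda = wts$lambda, temperature = Temp,
      train_loss = sums[["total"]] / n_train,
      loss_rec = sums[["rec"]] / n_train,
      loss_reg = sums[["reg"]] / n_train,
      loss_pass = sums[["pass"]] / n_train,
      val_rmse = val_rmse, val_r2 = val_r2, tau = model$state$tau)
  }

  model$params <- best_params              # best-validation checkpoint
  model$state$next_stage <- stage_id + 1L
  list(model = model, opt = opt, logs = do.call(rbind, logs),
       epoch_subsets = epoch_subsets)
}

#' Train the full three-stage joint model
#'
#' Builds an [hsi_model()] and runs Stages 0-2 on prepared patches,
#' fixing the deployable band subset between Stages 1 and 2.
#'
#' @param train_data,val_data lists of `list(x = (H,W,C) array, y)`.
#' @param n_bands band count C.
#' @param K target band budget.
#' @param plan a [stage_plan()].
#' @param base_width,hidden model capacity knobs (see [hsi_model()]).
#' @param seed integer seed.
#' @return list with `model`, `logs`, `epoch_subsets`, `selected_bands`
#'   (0-based indices of the fixed subset).
#' @export
train_joint <- function(train_data, val_data, n_bands, K,
                        plan = stage_plan(), base_width = 16L,
                        hidden = NULL, seed = 1L) {
  model <- hsi_model(n_bands, K, base_width = base_width, hidden = hidden,
                     seed = seed)
  ## centre the output at the training-label mean so the Huber residuals
  ## start inside the quadratic regime
  model$params$reg_head_b <- mean(vapply(train_data, function(s) s$y, 1))
  model$state$next_stage <- 0L
  opt <- NULL
  logs <- NULL
  subsets <- list()
  for (stage in 0:2) {
    out <- run_stage(model, stage, train_data, val_data, plan, opt = opt,
                     seed = (seed + 10007L * stage) %% 2147483647)
    model <- out$model
    opt <- out$opt
    logs <- rbind(logs, out$logs)
    subsets <- c(subsets, out$epoch_subsets)
  }
  list(model = model, logs = logs, epoch_subsets = subsets,
       selected_bands = model$state$hard_idx)
}

#' Preprocess one phantom sample into a network-ready patch
#'
#' Calibrates raw intensities with the sample's reference frames,
#' percentile-normalizes to `[0, 1]`, and extracts a square patch.
#'
#' @param sample a `phantom_sample` (or list with `cube`, `white_ref`,
#'   `dark_ref`).
#' @param patch_size patch edge length.
#' @param mode `"eval"` (center) or `"train"` (random, seeded).
#' @param seed crop seed for train mode.
#' @return normalized [hyper_cube()] patch.
#' @export
preprocess_sample <- function(sample, patch_size, mode = "eval",
                              seed = NULL) {
  cube <- hyper_cube(sample$cube, wavelengths = sample$wavelengths %||% NULL)
  cal <- calibrate_reflectance(cube, list(white = sample$white_ref,
                                          dark = sample$dark_ref))
  extract_patch(percentile_normalize(cal), size = patch_size, mode = mode,
                seed = seed)
}

## Patch list for the trainer from phantom samples.
patches_from_samples <- function(samples, labels, patch_size) {
  lapply(seq_along(samples), function(i) {
    p <- preprocess_sample(samples[[i]], patch_size)
    list(x = to_internal(p$values), y = labels[i])
  })
}

#' Evaluate a trained model on a prepared dataset
#'
#' Runs the deployable forward pass (hard band subset when fixed, soft
#' gate otherwise) over every sample, returning regression metrics and,
#' optionally, reconstruction metrics averaged over samples.
#'
#' @param model a trained [hsi_model()].
#' @param data list of `list(x = (H,W,C) array, y)`.
#' @param recon also compute reconstruction metrics.
#' @return list with `yhat`, `reg` ([reg_metrics()]), and `recon`
#'   (averaged [recon_metrics()] fields) when requested.
#' @export
evaluate_model <- function(model, data, recon = TRUE) {
  cfg <- model$config
  hard_gate <- if (!is.null(model$state$hard_idx))
    as.numeric((seq_len(cfg$n_bands) - 1L) %in% model$state$hard_idx)
  yhat <- numeric(length(data))
  rec_acc <- NULL
  for (i in seq_along(data)) {
    fw <- net_forward(model$params, data[[i]]$x, model$state$tau,
                      0.1, hard_gate = hard_gate, need_recon = recon,
                      Kbud = cfg$K)
    yhat[i] <- fw$yhat
    if (recon) {
      m <- recon_metrics(to_bandfirst(data[[i]]$x), to_bandfirst(fw$xhat))
      v <- unlist(m)
      rec_acc <- if (is.null(rec_acc)) v else rec_acc + v
    }
  }
  y <- vapply(data, function(s) s$y, 1)
  out <- list(yhat = yhat, reg = reg_metrics(y, yhat))
  if (recon) out$recon <- as.list(rec_acc / length(data))
  out
}

#' Band-budget sweep
#'
#' Trains a scaled-down joint model per candidate K and tabulates the
#' compactness trade-off: reconstruction MSE and prediction R-squared on
#' the validation set, plus min-max normalized columns for plotting.
#'
#' @param train_data,val_data prepared patch lists.
#' @param n_bands band count.
#' @param candidate_Ks at least two band budgets.
#' @param plan a [stage_plan()] (use a small epoch budget here).
#' @param seed integer seed.
#' @param base_width,hidden model capacity knobs.
#' @return data.frame with `K`, `rec_mse`, `reg_r2`, `rec_mse_norm`,
#'   `reg_r2_norm`.
#' @export
sweep_k <- function(train_data, val_data, n_bands, candidate_Ks,
                    plan = stage_plan(total_epochs = 8L,
                                      stage_epochs = c(4L, 2L, 2L)),
                    seed = 1L, base_width = 8L, hidden = NULL) {
  if (length(candidate_Ks) < 2) stopf("need at least 2 candidate K values")
  rows <- lapply(candidate_Ks, function(K) {
    fit <- train_joint(train_data, val_data, n_bands, K, plan = plan,
                       base_width = base_width, hidden = hidden,
                       seed = seed)
    ev <- evaluate_model(fit$model, val_data, recon = TRUE)
    data.frame(K = K, rec_mse = ev$recon$mse, reg_r2 = ev$reg$r2)
  })
  tab <- do.call(rbind, rows)
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }
  tab$rec_mse_norm <- norm01(tab$rec_mse)
  tab$reg_r2_norm <- norm01(tab$reg_r2)
  tab
}

#' End-to-end phantom experiment
#'
#' Generates a phantom dataset, balances the train/validation/test split,
#' preprocesses patches, trains the three-stage joint model, and evaluates
#' on the held-out test subset.
#'
#' @param config a [phantom_config()].
#' @param K band budget.
#' @param plan a [stage_plan()].
#' @param patch_size network patch edge (default `min(height, width)`
#'   rounded down to even).
#' @param ratio split ratio (default 8:1:1).
#' @param seed integer seed driving generation, split and training.
#' @param base_width,hidden model capacity knobs.
#' @param recon_metrics also compute test reconstruction metrics.
#' @return list with `model`, `logs`, `selected_bands`, `split`,
#'   `epoch_subsets`, `test` (evaluation results), `dataset`.
#' @export
phantom_run <- function(config, K, plan = stage_plan(),
                        patch_size = NULL, ratio = c(8, 1, 1), seed = 1L,
                        base_width = 16L, hidden = NULL,
                        recon_metrics = TRUE) {
  ds <- generate_dataset(config)
  patch_size <- patch_size %||%
    (min(config$height, config$width) %/% 2L * 2L)
  patches <- patches_from_samples(ds$samples, ds$manifest$ssc, patch_size)
  summaries <- lapply(seq_along(ds$samples), function(i) {
    p <- preprocess_sample(ds$samples[[i]], patch_size)
    summarize_sample(p, ds$manifest$ssc[i], id = ds$manifest$id[i])
  })
  sp <- balanced_split(summaries, ratio = ratio,
                       seed = (seed + 17L) %% 2147483647)
  sub <- sp$assignment$subset
  fit <- train_joint(patches[sub == "train"], patches[sub == "val"],
                     config$n_bands, K, plan = plan, seed = seed,
                     base_width = base_width, hidden = hidden)
  test_eval <- evaluate_model(fit$model, patches[sub == "test"],
                              recon = recon_metrics)
  c(fit, list(split = sp, test = test_eval, dataset = ds))
}
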