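#' Meta-learning configuration
#'
#' Holds the MAML optimization hyperparameters. Defaults follow the
#' published experimental setting: inner (task-adaptation) step size
#' \eqn{\alpha = 10^{-4}}, outer (meta) learning rate \eqn{\beta = 10^{-6}}
#' under Adam, weight decay \eqn{10^{-5}}, batch size 1, early-stopping
#' patience 20 for meta-training and 10 for meta-test fine-tuning.
#'
#' @param inner_lr inner-loop gradient-descent step size (alpha).
#' @param outer_lr outer-loop Adam learning rate (beta).
#' @param inner_steps inner gradient steps per episode (>= 1).
#' @param weight_decay L2 coefficient added to the outer gradient.
#' @param batch_size samples per forward pass (kept at 1; losses are
#'   averaged over the support/query sets regardless).
#' @param patience_meta_train epochs without query-DSC improvement tolerated
#'   before meta-training stops.
#' @param patience_fine_tune epochs without loss improvement tolerated
#'   before fine-tuning stops.
#' @param max_epochs,fine_tune_max_epochs hard epoch caps.
#' @param first_order if `TRUE`, drop the second-order term of the
#'   meta-gradient (cheaper; an approximation).
#' @param fine_tune_lr Adam learning rate for meta-test fine-tuning;
#'   defaults to `inner_lr`.
#' @param hvp_eps relative step for the finite-difference Hessian-vector
#'   products used by the second-order meta-gradient.
#' @param smooth Dice-loss smoothing constant.
#' @param seed master seed driving initialization, episode sampling and
#'   dropout.
#' @return A `meta_config` list.
#' @export
meta_config <- function(inner_lr = 1e-4, outer_lr = 1e-6, inner_steps = 1L,
                        weight_decay = 1e-5, batch_size = 1L,
                        patience_meta_train = 20L, patience_fine_tune = 10L,
                        max_epochs = 150L, fine_tune_max_epochs = 100L,
                        first_order = FALSE, fine_tune_lr = NULL,
                        hvp_eps = 1e-4, smooth = 1e-5, seed = 1L) {
  if (inner_lr < 0 || outer_lr <= 0) abort("learning rates must be positive.")
  if (inner_steps < 1) abort("`inner_steps` must be >= 1.")
  if (patience_meta_train < 1 || patience_fine_tune < 1) abort("patience must be >= 1.")
  structure(
    list(inner_lr = inner_lr, outer_lr = outer_lr,
         inner_steps = as.integer(inner_steps),
         weight_decay = weight_decay, batch_size = as.integer(batch_size),
         patience_meta_train = as.integer(patience_meta_train),
         patience_fine_tune = as.integer(patience_fine_tune),
         max_epochs = as.integer(max_epochs),
         fine_tune_max_epochs = as.integer(fine_tune_max_epochs),
         first_order = isTRUE(first_order),
         fine_tune_lr = fine_tune_lr %||% inner_lr,
         hvp_eps = hvp_eps, smooth = smooth, seed = as.integer(seed)),
    class = "meta_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a segmentation task
#'
#' A task is one segmentation problem — an organ, or a phantom family —
#' given as a pool of image/mask pairs from which episodes are drawn.
#'
#' @param name task label.
#' @param pool nonempty list of `list(image = volume, mask = binary_mask)`.
#' @return A `seg_task`.
#' @export
seg_task <- function(name, pool) {
  if (length(pool) < 1) abort("task pool must be nonempty.")
  ok <- vapply(pool, function(p) {
    !is.null(p$image) && !is.null(p$mask) &&
      identical(dim(p$image$data), dim(p$mask$data))
  }, TRUE)
  if (!all(ok)) abort("every pool entry needs shape-consistent $image and $mask.")
  structure(list(name = name, pool = pool), class = "seg_task")
}

#' @export
print.seg_task <- function(x, ...) {
  cat(sprintf("<seg_task> '%s': pool of %d image/mask pairs (%s voxels)\n",
              x$name, length(x$pool),
              paste(dim(x$pool[[1]]$image$data), collapse = "x")))
  invisible(x)
}

#' Sample a support/query episode from a task
#'
#' Draws `k_support + k_query` distinct pool members uniformly without
#' replacement and splits them into disjoint support and query sets — the
#' unit the MAML loop consumes.
#'
#' @param task a [seg_task()].
#' @param k_support,k_query set sizes (>= 1).
#' @param pool_idx optional subset of pool indices to draw from.
#' @param seed optional seed; `NULL` uses (and advances) the current RNG
#'   stream, which is how [meta_train()] keeps one master seed.
#' @return An `episode`: list with `task_name`, `support`, `query`,
#'   `support_idx`, `query_idx`.
#' @export
sample_episode <- function(task, k_support, k_query, pool_idx = NULL, seed = NULL) {
  stopifnot(inherits(task, "seg_task"))
  pool_idx <- pool_idx %||% seq_along(task$pool)
  need <- k_support + k_query
  if (length(pool_idx) < need) {
    abort(sprintf("task '%s' pool (%d available) is smaller than k_support + k_query = %d.",
                  task$name, length(pool_idx), need))
  }
  draw <- function() {
    picked <- sample(pool_idx, need, replace = FALSE)
    list(s = picked[seq_len(k_support)], q = picked[k_support + seq_len(k_query)])
  }
  idx <- if (is.null(seed)) draw() else with_preserved_rng(seed, draw())
  structure(
    list(task_name = task$name,
         support = task$pool[idx$s], query = task$pool[idx$q],
         support_idx = idx$s, query_idx = idx$q),
    class = "episode"
  )
}

# --- model abstraction ------------------------------------------------------
# The meta-learner only needs (params, loss+gradient); this generic lets the
# analytic toy models in the tests share the exact MAML code path with the
# full backbone.

model_lossgrad <- function(model, params, data, train = TRUE,
                           want_grad = TRUE, ...) {
  UseMethod("model_lossgrad")
}

#' @export
model_lossgrad.backbone_state <- function(model, params, data, train = TRUE,
                                          want_grad = TRUE, ...) {
  smooth <- list(...)$smooth %||% 1e-5
  backbone_loss_grad(model, params, data, train = train, smooth = smooth,
                     want_grad = want_grad)
}

#' Wrap an arbitrary differentiable loss as a meta-learnable model
#'
#' For analytic and toy experiments: `fn(params, data)` must return
#' `list(loss = scalar, grad = named list matching params)`.
#'
#' @param params named list of numeric arrays.
#' @param fn loss/gradient closure.
#' @return A `generic_model` usable by [inner_adapt()], [meta_step()], etc.
#' @export
generic_model <- function(params, fn) {
  structure(list(params = params, fn = fn), class = "generic_model")
}

#' @export
model_lossgrad.generic_model <- function(model, params, data, train = TRUE,
                                         want_grad = TRUE, ...) {
  model$fn(params, data)
}

set_params <- function(model, params) {
  model$params <- params
  model
}

# --- inner loop -------------------------------------------------------------

# gradient-descent trajectory theta_0 .. theta_S on the support loss
inner_trajectory <- function(model, support, cfg) {
  thetas <- vector("list", cfg$inner_steps + 1L)
  thetas[[1]] <- model$params
  for (s in seq_len(cfg$inner_steps)) {
    g <- model_lossgrad(model, thetas[[s]], support, train = TRUE,
                        smooth = cfg$smooth)
    thetas[[s + 1L]] <- params_axpy(thetas[[s]], -cfg$inner_lr, g$grad)
  }
  thetas
}

#' Inner-loop task adaptation
#'
#' Performs `inner_steps` plain gradient-descent updates
#' \eqn{\theta' = \theta - \alpha \nabla_\theta L(f_\theta)} on the mean
#' support-set Dice loss. The incoming model is never mutated.
#'
#' @param state a model (`backbone_state` or [generic_model()]).
#' @param support list of image/mask pairs (or whatever the model's loss
#'   consumes).
#' @param cfg a [meta_config()].
#' @return The adapted model carrying \eqn{\theta'}.
#' @export
inner_adapt <- function(state, support, cfg) {
  if (length(support) < 1) abort("support set must be nonempty.")
  thetas <- inner_trajectory(state, support, cfg)
  set_params(state, thetas[[length(thetas)]])
}

# finite-difference Hessian-vector product of the support loss at theta
hvp_fd <- function(model, theta, data, v, cfg) {
  nv <- params_norm(v)
  if (nv == 0) return(params_zero_like(v))
  h <- cfg$hvp_eps * (1 + params_norm(theta)) / nv
  gp <- model_lossgrad(model, params_axpy(theta, h, v), data, train = TRUE,
                       smooth = cfg$smooth)$grad
  gm <- model_lossgrad(model, params_axpy(theta, -h, v), data, train = TRUE,
                       smooth = cfg$smooth)$grad
  mapply(function(a, b) (a - b) / (2 * h), gp, gm, SIMPLIFY = FALSE)
}

#' Meta-objective over a batch of episodes
#'
#' \eqn{\sum_i L_{T_i}(f_{\theta_i'})}: each episode's support set adapts
#' \eqn{\theta} to \eqn{\theta_i'} via [inner_adapt()], and the loss is the
#' mean Dice loss of the adapted model on that episode's query set.
#'
#' @param state a model carrying \eqn{\theta}.
#' @param episodes list of [sample_episode()] results (one per task).
#' @param cfg a [meta_config()].
#' @return Scalar meta-loss.
#' @export
outer_objective <- function(state, episodes, cfg) {
  if (length(episodes) < 1) abort("need at least one episode.")
  sum(vapply(episodes, function(ep) {
    adapted <- inner_adapt(state, ep$support, cfg)
    model_lossgrad(adapted, adapted$params, ep$query, train = TRUE,
                   smooth = cfg$smooth, want_grad = FALSE)$loss
  }, 0))
}

#' Meta-gradient of the outer objective
#'
#' Back-propagates each episode's query gradient through the inner
#' gradient-descent trajectory. With `first_order = FALSE` the second-order
#' term is included by applying \eqn{(I - \alpha H_k)} at every inner step
#' \eqn{k} via Hessian-vector products (central finite differences of the
#' support gradient); with `first_order = TRUE` the query gradient at
#' \eqn{\theta'} is used directly.
#'
#' @inheritParams outer_objective
#' @return `list(loss = scalar meta-loss, grad = named gradient list)`.
#' @export
meta_gradient <- function(state, episodes, cfg) {
  if (length(episodes) < 1) abort("need at least one episode.")
  total <- NULL
  loss <- 0
  for (ep in episodes) {
    thetas <- inner_trajectory(state, ep$support, cfg)
    theta_ad <- thetas[[length(thetas)]]
    q <- model_lossgrad(state, theta_ad, ep$query, train = TRUE,
                        smooth = cfg$smooth)
    loss <- loss + q$loss
    v <- q$grad
    if (!cfg$first_order) {
      for (k in rev(seq_len(cfg$inner_steps))) {
        hv <- hvp_fd(state, thetas[[k]], ep$support, v, cfg)
        v <- params_axpy(v, -cfg$inner_lr, hv)
      }
    }
    total <- if (is.null(total)) v else params_axpy(total, 1, v)
  }
  list(loss = loss, grad = total)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = params_zero_like(params), v = params_zero_like(params),
       t = 0L, lr = lr, weight_decay = weight_decay,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_update <- function(opt, params, grad) {
  opt$t <- opt$t + 1L
  if (opt$weight_decay > 0) grad <- params_axpy(grad, opt$weight_decay, params)
  opt$m <- mapply(function(m, g) opt$beta1 * m + (1 - opt$beta1) * g,
                  opt$m, grad, SIMPLIFY = FALSE)
  opt$v <- mapply(function(v, g) opt$beta2 * v + (1 - opt$beta2) * g^2,
                  opt$v, grad, SIMPLIFY = FALSE)
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  new_params <- mapply(function(p, m, v) {
    p - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }, params, opt$m, opt$v, SIMPLIFY = FALSE)
  list(params = new_params, opt = opt)
}

#' One outer-loop meta-update
#'
#' Computes the (second-order, unless configured otherwise) meta-gradient of
#' the summed query losses and applies a single Adam step with learning rate
#' `outer_lr` and the configured weight decay to \eqn{\theta}.
#'
#' @inheritParams outer_objective
#' @param opt optimizer state from a previous call, or `NULL` to start.
#' @return `list(state, opt, meta_loss)`.
#' @export
meta_step <- function(state, episodes, cfg, opt = NULL) {
  mg <- meta_gradient(state, episodes, cfg)
  opt <- opt %||% adam_init(state$params, cfg$outer_lr, cfg$weight_decay)
  upd <- adam_update(opt, state$params, mg$grad)
  list(state = set_params(state, upd$params), opt = upd$opt,
       meta_loss = mg$loss)
}

# --- experiment plan --------------------------------------------------------

#' Assemble an experiment plan
#'
#' Mirrors the published split design: three meta-training tasks with
#' support/query/evaluation images, plus one held-out meta-test task with
#' `k` training shots and a disjoint test set.
#'
#' @param meta_train list of `list(task, episode_idx, n_support, n_query,
#'   eval_idx)`.
#' @param meta_test `list(task, train_idx, test_idx)`.
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(meta_train, meta_test) {
  if (length(meta_train) < 1) abort("need at least one meta-training task.")
  train_names <- vapply(meta_train, function(mt) mt$task$name, "")
  if (anyDuplicated(train_names)) abort("duplicate meta-training task names.")
  if (meta_test$task$name %in% train_names) {
    abort("the meta-test task must not appear among the meta-training tasks.")
  }
  for (mt in meta_train) {
    if (length(mt$episode_idx) < mt$n_support + mt$n_query) {
      abort(sprintf("task '%s': episode pool smaller than support + query.",
                    mt$task$name))
    }
    if (length(intersect(mt$episode_idx, mt$eval_idx)) > 0) {
      abort(sprintf("task '%s': evaluation images overlap the episode pool.",
                    mt$task$name))
    }
  }
  if (length(intersect(meta_test$train_idx, meta_test$test_idx)) > 0) {
    abort("meta-test training shots overlap the test set.")
  }
  structure(list(meta_train = meta_train, meta_test = meta_test),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat("<experiment_plan>\n  meta-train:\n")
  for (mt in x$meta_train) {
    cat(sprintf("    %-12s episodes %d/%d from pool of %d, eval %d\n",
                mt$task$name, mt$n_support, mt$n_query,
                length(mt$episode_idx), length(mt$eval_idx)))
  }
  cat(sprintf("  meta-test:  %-12s %d shot(s), %d test image(s)\n",
              x$meta_test$task$name, length(x$meta_test$train_idx),
              length(x$meta_test$test_idx)))
  invisible(x)
}

# mean DSC of eval-mode predictions over a set of pairs
mean_eval_dsc <- function(state, pairs) {
  mean(vapply(pairs, function(pr) {
    dice_score(predict_mask(state, pr$image), pr$mask)
  }, 0))
}

# --- the three phases -------------------------------------------------------

#' Meta-training (phase 1)
#'
#' Runs episodic MAML: each epoch samples one support/query episode per
#' meta-training task, applies one [meta_step()], then scores the current
#' \eqn{\theta} by mean evaluation-set DSC per task. Training stops when the
#' mean DSC has not improved for `patience_meta_train` consecutive epochs
#' (or at `max_epochs`), and the best-scoring parameters are returned — not
#' the last.
#'
#' @param plan an [experiment_plan()].
#' @param cfg a [meta_config()]; `cfg$seed` drives initialization, episode
#'   sampling and dropout.
#' @param backbone a [backbone_config()] for the fresh model; ignored when
#'   `init_state` is given.
#' @param init_state optional starting `backbone_state`.
#' @param verbose print per-epoch progress.
#' @return A `meta_train_result`: `state` (best \eqn{\theta'}), `history`
#'   (tibble: epoch, meta_loss, per-task query losses, mean_eval_dsc),
#'   `best_epoch`, `stopped_epoch`.
#' @export
meta_train <- function(plan, cfg, backbone = backbone_config(),
                       init_state = NULL, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"), inherits(cfg, "meta_config"))
  set.seed(cfg$seed)
  state <- init_state %||% build_backbone(backbone, rng_seed = cfg$seed)
  opt <- NULL
  history <- list()
  best_dsc <- -Inf
  best_params <- state$params
  best_epoch <- 0L
  since_best <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    episodes <- lapply(plan$meta_train, function(mt) {
      sample_episode(mt$task, mt$n_support, mt$n_query, pool_idx = mt$episode_idx)
    })
    st <- meta_step(state, episodes, cfg, opt)
    state <- st$state; opt <- st$opt
    task_dsc <- vapply(plan$meta_train, function(mt) {
      mean_eval_dsc(state, mt$task$pool[mt$eval_idx])
    }, 0)
    eval_dsc <- mean(task_dsc)
    history[[epoch]] <- c(
      list(epoch = epoch, meta_loss = st$meta_loss, mean_eval_dsc = eval_dsc),
      setNames(as.list(task_dsc), paste0("dsc_", vapply(plan$meta_train,
                                                        function(mt) mt$task$name, "")))
    )
    if (verbose) {
      message(sprintf("epoch %3d  meta-loss %.4f  eval DSC %.4f",
                      epoch, st$meta_loss, eval_dsc))
    }
    if (eval_dsc > best_dsc) {
      best_dsc <- eval_dsc
      best_params <- state$params
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience_meta_train) break
    }
  }
  structure(
    list(state = set_params(state, best_params),
         history = dplyr::bind_rows(history),
         best_epoch = best_epoch, best_dsc = best_dsc,
         stopped_epoch = length(history), config = cfg),
    class = "meta_train_result"
  )
}

#' Meta-test fine-tuning (phase 2)
#'
#' Standard (non-meta) Dice-loss training of \eqn{\theta'} on the `k`
#' training shots of an unseen task with Adam (`fine_tune_lr`, batch size 1),
#' early-stopped when the mean shot loss fails to improve for
#' `patience_fine_tune` epochs. The best checkpoint — including the
#' untouched \eqn{\theta'} itself, scored before any update — is returned.
#'
#' @param theta_prime the meta-trained model state.
#' @param task the held-out [seg_task()].
#' @param k number of training shots (the paper uses 5 or 10).
#' @param cfg a [meta_config()].
#' @param shot_idx explicit pool indices for the shots; when `NULL`, `k`
#'   are drawn with `seed`.
#' @param seed seed for the shot draw and dropout; defaults to `cfg$seed`.
#' @return A `fine_tune_result`: `state` (\eqn{\theta''}), `history`,
#'   `shot_idx`, `best_epoch`.
#' @export
fine_tune <- function(theta_prime, task, k, cfg, shot_idx = NULL, seed = NULL) {
  stopifnot(inherits(task, "seg_task"), inherits(cfg, "meta_config"))
  seed <- seed %||% cfg$seed
  set.seed(seed)
  if (is.null(shot_idx)) {
    if (length(task$pool) < k) {
      abort(sprintf("task '%s' pool too small for k = %d shots.", task$name, k))
    }
    shot_idx <- sample(seq_along(task$pool), k)
  }
  shots <- task$pool[shot_idx]
  state <- theta_prime
  opt <- adam_init(state$params, cfg$fine_tune_lr, cfg$weight_decay)
  base <- model_lossgrad(state, state$params, shots, train = FALSE,
                         smooth = cfg$smooth, want_grad = FALSE)$loss
  best_loss <- base
  best_params <- state$params
  best_epoch <- 0L
  since_best <- 0L
  history <- list(list(epoch = 0L, loss = base))
  for (epoch in seq_len(cfg$fine_tune_max_epochs)) {
    for (i in sample(seq_along(shots))) {
      g <- model_lossgrad(state, state$params, shots[i], train = TRUE,
                          smooth = cfg$smooth)
      upd <- adam_update(opt, state$params, g$grad)
      state <- set_params(state, upd$params)
      opt <- upd$opt
    }
    loss <- model_lossgrad(state, state$params, shots, train = FALSE,
                           smooth = cfg$smooth, want_grad = FALSE)$loss
    history[[epoch + 1L]] <- list(epoch = epoch, loss = loss)
    if (loss < best_loss) {
      best_loss <- loss
      best_params <- state$params
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience_fine_tune) break
    }
  }
  structure(
    list(state = set_params(state, best_params),
         history = dplyr::bind_rows(history),
         shot_idx = shot_idx, best_epoch = best_epoch,
         best_loss = best_loss),
    class = "fine_tune_result"
  )
}

#' Final testing (phase 3)
#'
#' Evaluation-mode forward passes with argmax binarization over a held-out
#' test set, reported as per-case and mean DSC / IoU / HD95.
#'
#' @param theta_dd the fine-tuned model state (\eqn{\theta''}).
#' @param test_pairs list of image/mask pairs disjoint from the shots.
#' @param ids optional case labels.
#' @return A `metric_report`.
#' @export
final_test <- function(theta_dd, test_pairs, ids = NULL) {
  if (length(test_pairs) < 1) abort("test set must be nonempty.")
  preds <- lapply(test_pairs, function(pr) predict_mask(theta_dd, pr$image))
  evaluate_masks(preds, lapply(test_pairs, `[[`, "mask"), ids = ids)
}

#' Run the full three-phase experiment
#'
#' Meta-train on the plan's source tasks, fine-tune on the held-out task's
#' shots, and test on its disjoint test images.
#'
#' @inheritParams meta_train
#' @return List with `meta` (`meta_train_result`), `tuned`
#'   (`fine_tune_result`), `report` (`metric_report`).
#' @export
run_experiment <- function(plan, cfg, backbone = backbone_config(),
                           verbose = FALSE) {
  mt <- meta_train(plan, cfg, backbone = backbone, verbose = verbose)
  ft <- fine_tune(mt$state, plan$meta_test$task, length(plan$meta_test$train_idx),
                  cfg, shot_idx = plan$meta_test$train_idx)
  rep <- final_test(ft$state, plan$meta_test$task$pool[plan$meta_test$test_idx],
                    ids = paste0(plan$meta_test$task$name, "_",
                                 plan$meta_test$test_idx))
  list(meta = mt, tuned = ft, report = rep)
}

# --- tidiers / plots --------------------------------------------------------

#' @export
tidy.meta_train_result <- function(x, ...) x$history

#' @export
glance.meta_train_result <- function(x, ...) {
  tibble(epochs = x$stopped_epoch, best_epoch = x$best_epoch,
         best_eval_dsc = x$best_dsc,
         final_meta_loss = x$history$meta_loss[nrow(x$history)])
}

#' @export
tidy.fine_tune_result <- function(x, ...) x$history

#' @export
glance.fine_tune_result <- function(x, ...) {
  tibble(epochs = max(x$history$epoch), best_epoch = x$best_epoch,
         best_loss = x$best_loss, k_shots = length(x$shot_idx))
}

#' Plot methods for training results and metric reports
#'
#' `autoplot.meta_train_result` draws the per-epoch evaluation DSC curve
#' (the learning curve of the meta-training phase);
#' `autoplot.fine_tune_result` the fine-tuning loss; and
#' `autoplot.metric_report` per-case metric bars.
#'
#' @param object the result object.
#' @param ... unused.
#' @return A ggplot.
#' @name autoplot_metaseg
NULL

#' @rdname autoplot_metaseg
#' @export
autoplot.meta_train_result <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$mean_eval_dsc)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "meta-epoch", y = "mean evaluation DSC",
                  title = "Meta-training learning curve") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_metaseg
#' @export
autoplot.fine_tune_result <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "epoch", y = "mean shot Dice loss",
                  title = "Meta-test fine-tuning") +
    ggplot2::theme_minimal()
}
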