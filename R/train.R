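#' Training schedule configuration
#'
#' The published recipe: pre-train with the L1-loss, then fine-tune with
#' the score-dependent epsilon-insensitive loss, optimised with Adam
#' (default parameters except the learning rate), batch size 70, and an
#' inverse-frequency imbalanced sampler over 10 equal-width score bins.
#' Setting \code{finetune_epochs_eps = 0} gives the pure-L1 ablation;
#' \code{pretrain_epochs_l1 = 0} gives the no-pre-training ablation.
#'
#' @param lr learning rate.
#' @param batch_size decoys per optimisation step.
#' @param pretrain_epochs_l1 epochs of L1 pre-training (phase 1).
#' @param finetune_epochs_eps epochs of epsilon-loss fine-tuning
#'   (phase 2).
#' @param seed seed controlling initialisation, sampling and dropout.
#' @param balanced_sampling use the inverse-bin-frequency sampler.
#' @param sampler_bins number of equal-width label bins for the sampler.
#' @return list of class \code{qa_training_config}.
#' @export
training_config <- function(lr = 0.001, batch_size = 70L,
                            pretrain_epochs_l1 = 50L,
                            finetune_epochs_eps = 10L,
                            seed = 1L, balanced_sampling = TRUE,
                            sampler_bins = 10L) {
  stopifnot(lr > 0, batch_size >= 1, pretrain_epochs_l1 >= 0,
            finetune_epochs_eps >= 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 pretrain_epochs_l1 = as.integer(pretrain_epochs_l1),
                 finetune_epochs_eps = as.integer(finetune_epochs_eps),
                 seed = as.integer(seed),
                 balanced_sampling = isTRUE(balanced_sampling),
                 sampler_bins = as.integer(sampler_bins)),
            class = "qa_training_config")
}

#' Inverse-frequency sampling weights for imbalanced score labels
#'
#' Labels are binned into \code{n_bins} equal-width bins on [0,1]; each
#' decoy is weighted by the inverse of its bin's population so every
#' non-empty bin is drawn with approximately equal probability.  With
#' all labels identical (degenerate) uniform weights are returned.
#'
#' @param labels scores in [0,1].
#' @param n_bins number of bins.
#' @return normalised sampling weights (sum 1), one per decoy.
#' @export
make_balanced_sampler <- function(labels, n_bins = 10L) {
  stopifnot(all(labels >= 0 & labels <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(labels, edges, rightmost.closed = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  if (sum(cnt > 0) <= 1L) {
    return(rep(1 / length(labels), length(labels)))
  }
  w <- 1 / cnt[bin]
  w / sum(w)
}

# ---- Adam ------------------------------------------------------------------

.qa_zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace",
                                    classes = c("matrix", "numeric", "integer"))

.qa_adam_state <- function(params) {
  list(m = .qa_grad_zero(params), v = .qa_grad_zero(params), t = 0L)
}

# zero-filled structure matching the gradient layout (trainable leaves only)
.qa_grad_zero <- function(params) {
  zl <- function(lyr) lapply(lyr[.qa_trainable(lyr)], function(x) x * 0)
  list(atom = lapply(params$atom, zl),
       residue = lapply(params$residue, zl),
       mlp = lapply(params$mlp, function(l) lapply(l, function(x) x * 0)))
}

.qa_trainable <- function(lyr) {
  setdiff(names(lyr), c("bn_mean", "bn_var"))
}

# params <- params - lr * adam(grads); walks atom/residue/mlp in lockstep
.qa_adam_step <- function(params, grads, state, lr,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (blk in c("atom", "residue", "mlp")) {
    for (l in seq_along(grads[[blk]])) {
      for (nm in names(grads[[blk]][[l]])) {
        g <- grads[[blk]][[l]][[nm]]
        m <- beta1 * state$m[[blk]][[l]][[nm]] + (1 - beta1) * g
        v <- beta2 * state$v[[blk]][[l]][[nm]] + (1 - beta2) * g^2
        state$m[[blk]][[l]][[nm]] <- m
        state$v[[blk]][[l]][[nm]] <- v
        params[[blk]][[l]][[nm]] <- params[[blk]][[l]][[nm]] -
          lr * (m / bc1) / (sqrt(v / bc2) + eps)
      }
    }
  }
  list(params = params, state = state)
}

.qa_grad_add <- function(acc, g) {
  for (blk in c("atom", "residue", "mlp")) {
    for (l in seq_along(g[[blk]])) {
      for (nm in names(g[[blk]][[l]])) {
        acc[[blk]][[l]][[nm]] <- acc[[blk]][[l]][[nm]] + g[[blk]][[l]][[nm]]
      }
    }
  }
  acc
}

.qa_grad_scale <- function(g, s) {
  for (blk in c("atom", "residue", "mlp")) {
    for (l in seq_along(g[[blk]])) {
      for (nm in names(g[[blk]][[l]])) {
        g[[blk]][[l]][[nm]] <- g[[blk]][[l]][[nm]] * s
      }
    }
  }
  g
}

# ---- training loop ---------------------------------------------------------

# mean eval-mode loss and predictions over a prepared dataset
.qa_eval_loss <- function(params, inputs, labels, mcfg, lcfg) {
  preds <- vapply(inputs, function(inp) {
    qa_forward(params, inp, mcfg, training = FALSE)$global_score
  }, numeric(1))
  list(loss = mean(qa_loss(labels, preds, lcfg)), preds = preds)
}

#' Train the quality network with the two-phase schedule
#'
#' Phase 1 optimises the L1-loss for \code{pretrain_epochs_l1} epochs;
#' phase 2 continues with the configured loss (by default the
#' score-dependent epsilon-insensitive loss) for
#' \code{finetune_epochs_eps} epochs.  The validation loss under the
#' active phase's loss is logged each epoch together with the phase-2
#' loss recomputed on the same checkpoint; model selection returns the
#' checkpoint minimising that recomputed phase-2 loss across all epochs.
#' Training and validation sets must not share targets.
#'
#' @param dataset list with \code{inputs} (list of
#'   \code{qa_decoy_input}), \code{labels} (scores in [0,1]) and
#'   \code{targets} (target id per decoy).
#' @param cfg a [training_config()].
#' @param mcfg a [model_config()].
#' @param lcfg a [loss_config()] for phase 2 (and selection).
#' @param val validation set, same shape as \code{dataset}.
#' @param init_params_warm optional \code{qa_params} to warm-start from
#'   (e.g. the best GDT-TS checkpoint when fine-tuning on lDDT labels).
#' @return list of class \code{qa_fit}: \code{params} (selected
#'   checkpoint), \code{history} (per-epoch data.frame with phase,
#'   train/validation losses and the selection loss), \code{best_epoch},
#'   and the configs.
#' @export
train <- function(dataset, cfg = training_config(), mcfg = model_config(),
                  lcfg = loss_config("modified_eps"), val,
                  init_params_warm = NULL) {
  stopifnot(length(dataset$inputs) == length(dataset$labels))
  if (length(dataset$inputs) == 0L) stop("empty dataset")
  overlap <- intersect(unique(dataset$targets), unique(val$targets))
  if (length(overlap) > 0L) {
    stop("validation targets overlap training targets: ",
         paste(overlap, collapse = ", "))
  }
  set.seed(cfg$seed)
  d_res_in <- ncol(dataset$inputs[[1]]$res_features)
  d_atom_in <- ncol(dataset$inputs[[1]]$atom_features)
  params <- if (is.null(init_params_warm)) {
    init_params(mcfg, d_atom_in, d_res_in, seed = cfg$seed)
  } else init_params_warm
  state <- .qa_adam_state(params)

  n <- length(dataset$inputs)
  w <- if (cfg$balanced_sampling) {
    make_balanced_sampler(dataset$labels, cfg$sampler_bins)
  } else rep(1 / n, n)

  phases <- c(rep("l1", cfg$pretrain_epochs_l1),
              rep("eps", cfg$finetune_epochs_eps))
  l1cfg <- loss_config("l1")
  history <- data.frame()
  checkpoints <- list()
  for (ep in seq_along(phases)) {
    phase <- phases[ep]
    phase_lcfg <- if (phase == "l1") l1cfg else lcfg
    order_idx <- sample.int(n, n, replace = TRUE, prob = w)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      acc <- .qa_grad_zero(params)
      bl <- 0
      for (i in b) {
        fwd <- qa_forward(params, dataset$inputs[[i]], mcfg, training = TRUE)
        params <- fwd$params   # batch-norm running statistics
        y <- dataset$labels[i]
        bl <- bl + qa_loss(y, fwd$global_score, phase_lcfg)
        dg <- .qa_loss_grad(y, fwd$global_score, phase_lcfg) / length(b)
        if (dg != 0) {
          acc <- .qa_grad_add(acc, qa_backward(params, dataset$inputs[[i]],
                                               mcfg, fwd, dg))
        }
      }
      st <- .qa_adam_step(params, acc, state, cfg$lr)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + bl / length(b)
    }
    ep_loss <- ep_loss / length(batches)
    ev_active <- .qa_eval_loss(params, val$inputs, val$labels, mcfg, phase_lcfg)
    sel_loss <- if (phase == "l1") {
      mean(qa_loss(val$labels, ev_active$preds, lcfg))
    } else ev_active$loss
    history <- rbind(history, data.frame(
      epoch = ep, phase = phase, train_loss = ep_loss,
      val_loss = ev_active$loss, selection_loss = sel_loss))
    checkpoints[[ep]] <- params
  }
  if (length(phases) == 0L) {
    checkpoints <- list(params)
    history <- data.frame(epoch = 0L, phase = "init", train_loss = NA,
                          val_loss = NA, selection_loss = NA)
  }
  best <- which.min(history$selection_loss)
  structure(list(params = checkpoints[[best]], best_epoch = best,
                 history = history, model_config = mcfg,
                 training_config = cfg, loss_config = lcfg),
            class = "qa_fit")
}

#' @export
print.qa_fit <- function(x, ...) {
  cat(sprintf("<qa_fit> %d epochs, best epoch %d (selection loss %.4f)\n",
              nrow(x$history), x$best_epoch,
              x$history$selection_loss[x$best_epoch]))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the parameters, the model configuration, the
#' feature-provider tag and the epsilon schedule, plus a format version;
#' loading validates that the stored feature dimensions match.
#'
#' @param fit a \code{qa_fit} (or list with \code{params},
#'   \code{model_config}, \code{loss_config}).
#' @param path destination file.
#' @param provider_name residue-feature provider tag recorded alongside.
#' @return \code{path} invisibly (save); the checkpoint list (load).
#' @export
save_checkpoint <- function(fit, path, provider_name = "onehot") {
  obj <- list(version = 1L, params = fit$params,
              model_config = fit$model_config,
              loss_config = fit$loss_config,
              provider = provider_name)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version) || obj$version != 1L) {
    stop("unsupported checkpoint version")
  }
  obj
}
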