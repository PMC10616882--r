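test_that("balanced sampler weights are inverse to bin population", {
  labels <- c(rep(0.05, 90), rep(0.95, 10))
  w <- make_balanced_sampler(labels, n_bins = 10)
  expect_equal(w[100] / w[1], 9, tolerance = 1e-12)
  expect_equal(sum(w), 1)

  # uniform labels across bins -> uniform weights
  lab_u <- rep(seq(0.05, 0.95, by = 0.1), each = 5)
  expect_true(all(abs(make_balanced_sampler(lab_u, 10) - 1 / 50) < 1e-12))

  # degenerate: all labels identical
  expect_equal(make_balanced_sampler(rep(0.4, 7), 10), rep(1 / 7, 7))
})

test_that("sampler draw frequencies match targets within 2%", {
  labels <- c(rep(0.05, 700), rep(0.45, 250), rep(0.95, 50))
  w <- make_balanced_sampler(labels, n_bins = 10)
  set.seed(123)
  draws <- sample.int(length(labels), 1e5, replace = TRUE, prob = w)
  bins <- cut(labels[draws], c(0, 0.1, 0.5, 1))
  freq <- as.numeric(table(bins)) / 1e5
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("global metrics match textbook formulas on a random fixture", {
  fx <- tiny_eval_fixture()
  r <- evaluate_global(fx$preds, fx$labels, fx$targets)
  # direct-formula oracles
  pear <- function(a, b) {
    n <- length(a)
    (sum(a * b) - n * mean(a) * mean(b)) /
      sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  }
  expect_equal(r$R, pear(fx$preds, fx$labels), tolerance = 1e-12)
  expect_equal(r$rho, pear(rank(fx$preds), rank(fx$labels)), tolerance = 1e-12)
  expect_equal(r$RMSE, sqrt(mean((fx$preds - fx$labels)^2)), tolerance = 1e-12)
  rt <- mean(sapply(split(seq_along(fx$labels), fx$targets), function(ix)
    pear(fx$preds[ix], fx$labels[ix])))
  expect_equal(r$R_target, rt, tolerance = 1e-12)

  # identities
  p <- evaluate_global(fx$labels, fx$labels, fx$targets)
  expect_equal(p$R, 1); expect_equal(p$rho, 1); expect_equal(p$RMSE, 0)
  a <- evaluate_global(1 - fx$labels, fx$labels, fx$targets)
  expect_equal(a$R, -1)
})

test_that("constant-label targets are skipped in R_target with a count", {
  labels <- c(0.5, 0.5, 0.5, 0.2, 0.8)
  preds <- c(0.4, 0.6, 0.5, 0.25, 0.7)
  targets <- c("A", "A", "A", "B", "B")
  r <- evaluate_global(preds, labels, targets)
  expect_equal(r$n_skipped_targets, 1L)
  expect_equal(r$R_target, cor(preds[4:5], labels[4:5]))
})

test_that("local metrics match pair-counting and pROC oracles", {
  pred <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  lab <- c(0.9, 0.5, 0.8, 0.3, 0.7, 0.2)
  r <- evaluate_local(pred, lab, threshold = 0.6)
  pos <- lab >= 0.6
  # exhaustive pair counting (concordant + half ties over all pos/neg pairs)
  num <- 0; den <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    den <- den + 1
    num <- num + (pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j])
  }
  expect_equal(r$auroc, num / den, tolerance = 1e-12)
  expect_equal(r$R_local, cor(pred, lab), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    proc <- as.numeric(pROC::auc(pROC::roc(pos, pred, quiet = TRUE,
                                           direction = "<")))
    expect_equal(r$auroc, proc, tolerance = 1e-12)
  }
  # perfect predictions
  perf <- evaluate_local(lab, lab)
  expect_equal(perf$R_local, 1); expect_equal(perf$auroc, 1)
  expect_equal(perf$aupr, 1)
  # single-class labels -> undefined, reported as missing
  expect_true(is.na(evaluate_local(pred, rep(0.9, 6))$auroc))
})

test_that("label-independent predictions give AUROC near 0.5", {
  set.seed(5)
  lab <- runif(4000)
  pred <- runif(4000)
  r <- evaluate_local(pred, lab)
  expect_lt(abs(r$auroc - 0.5), 0.03)
})

test_that("AUPR matches exhaustive step-wise average precision", {
  set.seed(8)
  pred <- round(runif(40), 2)  # forces some score ties
  lab <- as.numeric(runif(40) < 0.4) * 0.9
  r <- evaluate_local(pred, lab, threshold = 0.6)
  pos <- lab >= 0.6
  # oracle: walk unique thresholds from high to low
  ths <- sort(unique(pred), decreasing = TRUE)
  rec0 <- 0; ap <- 0
  for (t in ths) {
    sel <- pred >= t
    prec <- sum(pos[sel]) / sum(sel)
    rec <- sum(pos[sel]) / sum(pos)
    ap <- ap + (rec - rec0) * prec
    rec0 <- rec
  }
  expect_equal(r$aupr, ap, tolerance = 1e-12)
})

make_micro_dataset <- function(seed = 1) {
  ds <- generate_dataset(synthetic_config(
    n_targets = 4L, decoys_per_target = 6L, chain_length_range = c(12L, 16L),
    noise_grades = c(0.2, 1, 3), seed = seed))
  prepare_training_data(ds, "lddt_global", val_fraction = 0.25, seed = seed)
}

micro_model <- function() model_config(
  n_layers_atom = 2, n_layers_residue = 2, hidden_dim_atom = 8,
  hidden_dim_residue = 8, mlp_hidden_dims = 8L)

test_that("training is deterministic given a seed and selects the argmin", {
  sp <- make_micro_dataset(3)
  tcfg <- training_config(pretrain_epochs_l1 = 2, finetune_epochs_eps = 2,
                          batch_size = 8, seed = 11)
  f1 <- train(sp$train, tcfg, micro_model(), loss_config("modified_eps"),
              val = sp$val)
  f2 <- train(sp$train, tcfg, micro_model(), loss_config("modified_eps"),
              val = sp$val)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$best_epoch, which.min(f1$history$selection_loss))
  expect_equal(f1$history$phase, c("l1", "l1", "eps", "eps"))
})

test_that("train rejects overlapping train/validation targets", {
  sp <- make_micro_dataset(4)
  bad_val <- sp$val
  bad_val$targets[1] <- sp$train$targets[1]
  expect_error(train(sp$train,
                     training_config(pretrain_epochs_l1 = 1,
                                     finetune_epochs_eps = 0, seed = 1),
                     micro_model(), loss_config(), val = bad_val),
               "overlap")
})

test_that("phase configuration reproduces the ablation recipes", {
  sp <- make_micro_dataset(5)
  # pure-L1 model: no epsilon fine-tuning phase
  f_l1 <- train(sp$train,
                training_config(pretrain_epochs_l1 = 2,
                                finetune_epochs_eps = 0, batch_size = 8,
                                seed = 2),
                micro_model(), loss_config("modified_eps"), val = sp$val)
  expect_true(all(f_l1$history$phase == "l1"))
  # no-pre-training ablation: straight to the epsilon loss
  f_eps <- train(sp$train,
                 training_config(pretrain_epochs_l1 = 0,
                                 finetune_epochs_eps = 2, batch_size = 8,
                                 seed = 2),
                 micro_model(), loss_config("modified_eps"), val = sp$val)
  expect_true(all(f_eps$history$phase == "eps"))
  # constant-epsilon and L2-only ablations run under the same interface
  for (k in c("constant_eps", "l2")) {
    f <- train(sp$train,
               training_config(pretrain_epochs_l1 = 0,
                               finetune_epochs_eps = 1, batch_size = 8,
                               seed = 2),
               micro_model(), loss_config(k), val = sp$val)
    expect_s3_class(f, "qa_fit")
  }
  # single-stream ablations
  for (mc in list(model_config(n_layers_atom = 2, n_layers_residue = 2,
                               hidden_dim_atom = 8, hidden_dim_residue = 8,
                               mlp_hidden_dims = 8L,
                               use_residue_stream = FALSE),
                  model_config(n_layers_atom = 2, n_layers_residue = 2,
                               hidden_dim_atom = 8, hidden_dim_residue = 8,
                               mlp_hidden_dims = 8L,
                               use_atom_stream = FALSE))) {
    f <- train(sp$train,
               training_config(pretrain_epochs_l1 = 1,
                               finetune_epochs_eps = 1, batch_size = 8,
                               seed = 3),
               mc, loss_config(), val = sp$val)
    expect_s3_class(f, "qa_fit")
  }
})
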