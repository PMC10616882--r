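#' Binned tube-width schedule for the score-dependent epsilon-insensitive loss
#'
#' The tube half-width is a non-increasing step function of the true
#' score y: poor decoys (low y) sit in a wide tube and are only loosely
#' fitted, while near-native decoys (y > 0.8) must be predicted to
#' within a few hundredths.  Three built-in settings (\code{low},
#' \code{mid}, \code{high}) shift all nine bin values together; \code{mid}
#' is the default used for training.
#'
#' @param setting \code{"low"}, \code{"mid"} or \code{"high"}, or
#'   \code{"custom"} with \code{eps_values} supplied.
#' @param eps_values for \code{"custom"}: 9 non-negative, non-increasing
#'   values, one per score bin.
#' @return list of class \code{qa_epsilon_schedule} with
#'   \code{bin_edges} (0, 0.1, ..., 0.8, 1.0) and \code{eps_values}.
#' @export
#' @examples
#' epsilon_of(0.85, epsilon_schedule("mid"))  # 0.01
epsilon_schedule <- function(setting = c("mid", "low", "high", "custom"),
                             eps_values = NULL) {
  setting <- match.arg(setting)
  presets <- list(
    low  = c(0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10, 0.05, 0.005),
    mid  = c(0.45, 0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.10, 0.01),
    high = c(0.50, 0.45, 0.40, 0.35, 0.30, 0.25, 0.20, 0.15, 0.015))
  if (setting == "custom") {
    stopifnot(!is.null(eps_values))
  } else {
    eps_values <- presets[[setting]]
  }
  eps_values <- as.numeric(eps_values)
  stopifnot(length(eps_values) == 9L, all(eps_values >= 0),
            all(diff(eps_values) <= 0))
  structure(list(bin_edges = c(seq(0, 0.8, by = 0.1), 1.0),
                 eps_values = eps_values, setting = setting),
            class = "qa_epsilon_schedule")
}

#' Tube half-width at a true score
#'
#' Bins are half-open \code{[edge_k, edge_{k+1})}; the last bin
#' (score > 0.8) is closed at 1.
#'
#' @param y true score(s) in [0,1] (vectorised).
#' @param schedule an [epsilon_schedule()].
#' @return epsilon value(s), non-negative.
#' @export
epsilon_of <- function(y, schedule = epsilon_schedule("mid")) {
  stopifnot(inherits(schedule, "qa_epsilon_schedule"))
  if (any(y < 0 | y > 1)) stop("y must lie in [0,1]")
  bin <- findInterval(y, schedule$bin_edges, rightmost.closed = TRUE)
  schedule$eps_values[bin]
}

#' The score-dependent epsilon-insensitive loss
#'
#' \code{max(0, |y - y_pred| - epsilon(y))}: zero inside a tube of
#' half-width epsilon(y) around the true score, growing linearly (slope
#' 1, like the L1-loss) outside.  The tube width depends on the true
#' score only, so gradients with respect to the prediction are the
#' L1 subgradient masked by tube membership.
#'
#' @param y true score(s) in [0,1].
#' @param y_pred predicted score(s), same length.
#' @param schedule an [epsilon_schedule()].
#' @param reduce \code{"mean"}, \code{"sum"} or \code{"none"}.
#' @return loss value(s), non-negative.
#' @export
modified_eps_loss <- function(y, y_pred, schedule = epsilon_schedule("mid"),
                              reduce = c("mean", "sum", "none")) {
  reduce <- match.arg(reduce)
  stopifnot(length(y) == length(y_pred))
  l <- pmax(0, abs(y - y_pred) - epsilon_of(y, schedule))
  switch(reduce, mean = mean(l), sum = sum(l), none = l)
}

#' Loss configuration for training and the ablation baselines
#'
#' @param kind \code{"modified_eps"} (the score-dependent tube),
#'   \code{"constant_eps"} / \code{"standard_eps"} (fixed tube width
#'   \code{constant_eps_value}), \code{"l1"} or \code{"l2"}.
#' @param schedule an [epsilon_schedule()] (used by
#'   \code{modified_eps}).
#' @param constant_eps_value fixed tube half-width (default 0.2).
#' @return list of class \code{qa_loss_config}.
#' @export
loss_config <- function(kind = c("modified_eps", "constant_eps", "l1", "l2",
                                 "standard_eps"),
                        schedule = epsilon_schedule("mid"),
                        constant_eps_value = 0.2) {
  kind <- match.arg(kind)
  stopifnot(constant_eps_value >= 0)
  structure(list(kind = kind, schedule = schedule,
                 constant_eps_value = constant_eps_value),
            class = "qa_loss_config")
}

#' Evaluate a training loss (vectorised, no reduction)
#'
#' @param y true score(s); @param y_pred predicted score(s).
#' @param cfg a [loss_config()].
#' @return per-observation losses.
#' @export
qa_loss <- function(y, y_pred, cfg = loss_config("modified_eps")) {
  r <- y_pred - y
  switch(cfg$kind,
    l1 = abs(r),
    l2 = r^2,
    modified_eps = pmax(0, abs(r) - epsilon_of(y, cfg$schedule)),
    constant_eps = ,
    standard_eps = pmax(0, abs(r) - cfg$constant_eps_value))
}

# dLoss/dy_pred (subgradient; tube boundary uses the inside-tube
# convention, gradient 0)
.qa_loss_grad <- function(y, y_pred, cfg) {
  r <- y_pred - y
  switch(cfg$kind,
    l1 = sign(r),
    l2 = 2 * r,
    modified_eps = sign(r) * (abs(r) > epsilon_of(y, cfg$schedule)),
    constant_eps = ,
    standard_eps = sign(r) * (abs(r) > cfg$constant_eps_value))
}

#' Baseline losses used in the ablation study
#'
#' Convenience wrapper over [qa_loss()] matching the ablation
#' configurations: plain L1, plain L2, and the standard (constant-width)
#' epsilon-insensitive loss.
#'
#' @inheritParams qa_loss
#' @param reduce \code{"mean"}, \code{"sum"} or \code{"none"}.
#' @return reduced loss.
#' @export
baseline_loss <- function(y, y_pred, cfg, reduce = c("mean", "sum", "none")) {
  reduce <- match.arg(reduce)
  l <- qa_loss(y, y_pred, cfg)
  switch(reduce, mean = mean(l), sum = sum(l), none = l)
}
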