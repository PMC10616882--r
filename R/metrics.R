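#' Global evaluation metrics for decoy-level predictions
#'
#' @param predictions predicted global scores, one per decoy.
#' @param labels true global scores, same order.
#' @param target_ids target identifier per decoy.
#' @return list with \code{R} (pooled Pearson), \code{R_target}
#'   (unweighted mean of within-target Pearson; targets whose labels
#'   have zero variance are skipped and counted in
#'   \code{n_skipped_targets}), \code{rho} (pooled Spearman) and
#'   \code{RMSE} on the [0,1] scale.
#' @export
evaluate_global <- function(predictions, labels, target_ids) {
  stopifnot(length(predictions) == length(labels),
            length(labels) == length(target_ids))
  per_target <- split(seq_along(labels), target_ids)
  rt <- vapply(per_target, function(ix) {
    if (length(ix) < 2L || sd(labels[ix]) == 0 || sd(predictions[ix]) == 0) {
      return(NA_real_)
    }
    cor(predictions[ix], labels[ix])
  }, numeric(1))
  list(R = cor(predictions, labels),
       R_target = mean(rt, na.rm = TRUE),
       n_skipped_targets = sum(is.na(rt)),
       rho = cor(predictions, labels, method = "spearman"),
       RMSE = sqrt(mean((predictions - labels)^2)))
}

# Mann-Whitney AUROC with tie handling via midranks
.qa_auroc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# area under the precision-recall curve (step-wise average precision;
# ties grouped so equal scores enter together)
.qa_aupr <- function(score, positive) {
  n1 <- sum(positive)
  if (n1 == 0L || all(positive)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- positive[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(as.numeric(p), grp, sum)
  n_g <- tapply(rep(1, length(p)), grp, sum)
  tp <- cumsum(tp_g); nn <- cumsum(n_g)
  prec <- tp / nn
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Local (per-residue) evaluation metrics
#'
#' Residue-level predictions pooled over decoys are scored against true
#' per-residue lDDT: Pearson correlation, and AUROC / AUPR for
#' recognising confidently modelled residues, binarised at a true local
#' lDDT of \code{threshold} (the CAMEO convention, 0.6).
#'
#' @param pred_res predicted per-residue scores (pooled vector).
#' @param label_res true per-residue lDDT, same order; NA entries
#'   (residues without qualifying pairs) are dropped pairwise.
#' @param threshold binarisation cutoff on the true local score.
#' @return list with \code{R_local}, \code{auroc}, \code{aupr}
#'   (\code{NA} when only one class is present).
#' @export
evaluate_local <- function(pred_res, label_res, threshold = 0.6) {
  stopifnot(length(pred_res) == length(label_res))
  ok <- !is.na(label_res) & !is.na(pred_res)
  pred_res <- pred_res[ok]; label_res <- label_res[ok]
  pos <- label_res >= threshold
  list(R_local = if (sd(label_res) == 0 || sd(pred_res) == 0) NA_real_ else
         cor(pred_res, label_res),
       auroc = .qa_auroc(pred_res, pos),
       aupr = .qa_aupr(pred_res, pos))
}
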