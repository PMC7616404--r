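# Segmentation-style evaluation of anomaly score maps: best-achievable DICE
# over a threshold sweep and the area under the precision-recall curve.
# Both metrics depend only on the ranking of scores, so they are invariant
# to strictly monotone transforms of the map.

#' Best-achievable DICE over all score thresholds
#'
#' Predictions are `score >= threshold`; the sweep uses the finite set of
#' observed score values, which attains the exact maximum over achievable
#' thresholdings. A truth mask with no positive voxel is undefined and is
#' excluded from corpus means.
#'
#' @param score numeric score map (array or vector).
#' @param truth binary truth mask of the same length.
#' @return list `dice`, `threshold`, and `undefined` flag.
#' @export
best_dice <- function(score, truth) {
  s <- as.numeric(score); y <- as.numeric(truth)
  if (length(s) != length(y)) stop("score / truth shape mismatch")
  if (!all(y %in% c(0, 1))) stop("truth mask must be binary")
  P <- sum(y)
  if (P == 0) return(list(dice = NA_real_, threshold = NA_real_, undefined = TRUE))
  o <- order(s, decreasing = TRUE)
  ys <- y[o]; ss <- s[o]
  tp <- cumsum(ys)
  rank <- seq_along(ys)
  # evaluate only at the last element of each tied-score group
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  dice <- 2 * tp[last] / (P + rank[last])
  i <- which.max(dice)
  list(dice = dice[i], threshold = ss[last][i], undefined = FALSE)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) summation over score-sorted voxels with tied
#' scores collapsed into single PR points: `sum (R_g - R_{g-1}) * P_g`.
#' Constant scores therefore yield the lesion prevalence.
#'
#' @param score numeric score map.
#' @param truth binary truth mask with at least one positive voxel.
#' @return scalar AUPRC (or `NA` with a warning if truth has no positives).
#' @export
auprc <- function(score, truth) {
  s <- as.numeric(score); y <- as.numeric(truth)
  if (length(s) != length(y)) stop("score / truth shape mismatch")
  if (!all(y %in% c(0, 1))) stop("truth mask must be binary")
  P <- sum(y)
  if (P == 0) { warning("truth has no positives; AUPRC undefined"); return(NA_real_) }
  o <- order(s, decreasing = TRUE)
  ys <- y[o]; ss <- s[o]
  tp <- cumsum(ys)
  rank <- seq_along(ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)
  recall <- tp[last] / P
  precision <- tp[last] / rank[last]
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate anomaly maps over a corpus
#'
#' @param cases named list; each element `list(score=, truth=)`.
#' @param csv optional path: writes one row per case plus a summary row.
#' @return data.frame with per-case `best_dice`, `threshold`, `auprc`, and
#'   attributes `mean_dice`, `sd_dice`, `mean_auprc`, `sd_auprc` (cases with
#'   empty truth are excluded from the summary).
#' @export
evaluate_corpus <- function(cases, csv = NULL) {
  ids <- names(cases) %||% as.character(seq_along(cases))
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    bd <- best_dice(cs$score, cs$truth)
    ap <- if (sum(cs$truth) > 0) auprc(cs$score, cs$truth) else NA_real_
    data.frame(id = ids[i], best_dice = bd$dice, threshold = bd$threshold,
               auprc = ap, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ok <- !is.na(df$best_dice)
  attr(df, "mean_dice") <- mean(df$best_dice[ok])
  attr(df, "sd_dice") <- stats::sd(df$best_dice[ok])
  attr(df, "mean_auprc") <- mean(df$auprc[ok])
  attr(df, "sd_auprc") <- stats::sd(df$auprc[ok])
  if (!is.null(csv)) {
    out <- rbind(df, data.frame(id = "summary_mean",
                                best_dice = attr(df, "mean_dice"),
                                threshold = NA_real_,
                                auprc = attr(df, "mean_auprc")))
    utils::write.csv(out, csv, row.names = FALSE)
  }
  df
}
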