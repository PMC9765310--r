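# Clinical evaluation stack: Dice overlap, vertical cup-to-disc ratio (CDR)
# and its absolute error delta, ROC/AUC for glaucoma screening, and the
# weighted-rank challenge score used by segmentation challenges.

binarize <- function(x, threshold = 0.5) {
  (x >= threshold) * 1
}

#' Dice similarity coefficient
#'
#' `DSC = 2 TP / (2 TP + FP + FN)` on binarized masks.  When both masks are
#' empty there is nothing to segment and the score is 1 by convention (the
#' prediction is vacuously perfect); this convention is needed for
#' degenerate synthetic cases and is stated here for reproducibility.
#'
#' @param pred predicted mask channel (probabilities or binary); binarized
#'   at `threshold`.
#' @param gt ground-truth binary mask channel.
#' @param threshold binarization threshold for `pred`.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(pred, gt, threshold = 0.5) {
  if (!all(dim(pred) == dim(gt))) stop("dsc: shape mismatch", call. = FALSE)
  p <- binarize(pred, threshold)
  g <- binarize(gt, threshold)
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# row extent (number of rows spanned) of the largest connected component
largest_component_row_extent <- function(channel) {
  if (sum(channel) == 0) return(0L)
  lab <- EBImage::bwlabel(channel)
  tab <- tabulate(lab[lab > 0])
  if (length(tab) == 0 || max(tab) == 0) return(0L)
  keep <- which.max(tab)
  rows <- which(apply(lab == keep, 1, any))
  diff(range(rows)) + 1L
}

#' Vertical cup-to-disc ratio of a segmentation mask
#'
#' Ratio of the vertical diameters `d(OC) / d(OD)`, each measured as the row
#' extent of the largest connected component of the corresponding channel
#' (robust to speckle in thresholded predictions).
#'
#' @param mask `H x W x 2` array (disc, cup), probabilities or binary;
#'   binarized at 0.5.
#' @return scalar CDR in `[0, 1]` whenever the cup is inside the disc.
#' @export
vertical_cdr <- function(mask) {
  disc <- binarize(mask[, , 1])
  cup <- binarize(mask[, , 2])
  d_od <- largest_component_row_extent(disc)
  if (d_od == 0) stop("vertical_cdr: empty disc channel, CDR undefined",
                      call. = FALSE)
  d_oc <- largest_component_row_extent(cup)
  if (d_oc == 0) {
    warning("vertical_cdr: empty cup channel, returning CDR 0")
    return(0)
  }
  d_oc / d_od
}

#' Absolute CDR error between predicted and reference masks
#'
#' @param pred,gt `H x W x 2` masks.
#' @return `delta = |CDR_pred - CDR_gt| >= 0`.
#' @export
cdr_delta <- function(pred, gt) {
  abs(vertical_cdr(pred) - vertical_cdr(gt))
}

#' ROC curve and AUC
#'
#' The curve is traced by sweeping the decision threshold over the unique
#' scores and computing the true/false positive rates; the area under it is
#' integrated by the trapezoid rule, which makes it equal to the
#' Mann-Whitney probability that a random positive outscores a random
#' negative (ties counted half).
#'
#' @param scores numeric screening scores (here typically predicted CDR).
#' @param labels 0/1 class labels, both classes present.
#' @return `list(curve, auc)`; `curve` is a data frame with `threshold`,
#'   `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("roc_auc: both classes must be present", call. = FALSE)
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 1) / pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 0) / neg,
                numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Weighted-rank challenge score
#'
#' Combines per-metric ranks into one score,
#' `R = 0.35 R_cup + 0.25 R_disc + 0.4 R_delta`; lower is better and a team
#' ranked first on everything scores exactly 1.
#'
#' @param rank_cup,rank_disc,rank_delta per-metric ranks (>= 1).
#' @return the weighted score.
#' @export
challenge_score <- function(rank_cup, rank_disc, rank_delta) {
  if (any(c(rank_cup, rank_disc, rank_delta) < 1)) {
    stop("challenge_score: ranks must be >= 1", call. = FALSE)
  }
  0.35 * rank_cup + 0.25 * rank_disc + 0.4 * rank_delta
}

#' Rank teams and compute their challenge scores
#'
#' Higher Dice ranks better (rank 1), lower delta ranks better; exact ties
#' receive average ranks.  Teams with a missing metric are excluded with a
#' warning.
#'
#' @param table data frame with columns `team`, `dsc_cup`, `dsc_disc`,
#'   `delta`.
#' @return the input plus `rank_cup`, `rank_disc`, `rank_delta`, `score`,
#'   sorted by score.
#' @export
rank_teams <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("team", "dsc_cup", "dsc_disc", "delta") %in% names(table)))
  if (nrow(table) < 2) stop("rank_teams: need at least two teams",
                            call. = FALSE)
  ok <- stats::complete.cases(table[, c("dsc_cup", "dsc_disc", "delta")])
  if (any(!ok)) {
    warning("rank_teams: excluding teams with missing metrics: ",
            paste(table$team[!ok], collapse = ", "))
    table <- table[ok, , drop = FALSE]
  }
  table$rank_cup <- rank(-table$dsc_cup, ties.method = "average")
  table$rank_disc <- rank(-table$dsc_disc, ties.method = "average")
  table$rank_delta <- rank(table$delta, ties.method = "average")
  table$score <- challenge_score(table$rank_cup, table$rank_disc,
                                 table$rank_delta)
  table[order(table$score), , drop = FALSE]
}

#' Evaluate one predicted mask against its reference
#'
#' @param pred,gt `H x W x 2` masks (disc, cup).
#' @return one-row data frame with Dice per structure, predicted and
#'   reference CDR, `delta`, and per-structure pixel counts.
#' @export
evaluate_pair <- function(pred, gt) {
  counts <- function(p, g) {
    p <- binarize(p); g <- binarize(g)
    c(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g))
  }
  cd <- counts(pred[, , 1], gt[, , 1])
  cc <- counts(pred[, , 2], gt[, , 2])
  # an empty predicted disc leaves the CDR undefined; recorded as NA so one
  # degenerate prediction does not abort a whole evaluation run
  cdr_p <- tryCatch(suppressWarnings(vertical_cdr(pred)),
                    error = function(e) NA_real_)
  cdr_g <- vertical_cdr(gt)
  data.frame(dsc_disc = dsc(pred[, , 1], gt[, , 1]),
             dsc_cup = dsc(pred[, , 2], gt[, , 2]),
             cdr_pred = cdr_p, cdr_gt = cdr_g, delta = abs(cdr_p - cdr_g),
             tp_disc = cd["tp"], fp_disc = cd["fp"], fn_disc = cd["fn"],
             tn_disc = cd["tn"], tp_cup = cc["tp"], fp_cup = cc["fp"],
             fn_cup = cc["fn"], tn_cup = cc["tn"], row.names = NULL)
}

#' Evaluate a list of predictions
#'
#' @param preds,gts lists of `H x W x 2` masks of equal length.
#' @return `list(records, summary)` — per-image rows and mean/sd aggregates.
#' @export
evaluate_predictions <- function(preds, gts) {
  stopifnot(length(preds) == length(gts))
  records <- do.call(rbind, Map(evaluate_pair, preds, gts))
  num <- records[, c("dsc_disc", "dsc_cup", "delta")]
  summary <- data.frame(metric = names(num),
                        mean = vapply(num, mean, numeric(1), na.rm = TRUE),
                        sd = vapply(num, sd, numeric(1), na.rm = TRUE),
                        row.names = NULL)
  list(records = records, summary = summary)
}
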