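#' Intersection over union of two binary masks
#'
#' `|a AND b| / |a OR b|`, defined as 0 when both masks are empty.
#' @param a,b Logical (or 0/1) matrices of identical shape.
#' @return A fraction in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Match predicted to ground-truth instances at an IoU threshold
#'
#' Candidate pairs are those with IoU strictly above `tau`; they are
#' accepted greedily in descending IoU order (ties broken by predicted then
#' truth label), each instance matched at most once. Matched pairs are true
#' positives; unmatched predictions are false positives and unmatched truth
#' instances false negatives.
#'
#' @param pred,truth Integer label maps of identical shape (0 = background).
#' @param tau IoU threshold in (0, 1].
#' @return List of class `cd_match` with `tau`, `TP`, `FP`, `FN`, and
#'   `pairs` (data.frame of matched pred/truth labels with IoU).
#' @export
match_instances <- function(pred, truth, tau) {
  if (!identical(dim(pred), dim(truth))) stop("label map shapes differ")
  stopifnot(tau > 0, tau <= 1)
  pl <- sort(unique(pred[pred > 0L]))
  tl <- sort(unique(truth[truth > 0L]))
  pairs <- data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  if (length(pl) > 0L && length(tl) > 0L) {
    # pairwise intersections from the joint histogram of foreground pixels
    fg <- pred > 0L & truth > 0L
    if (any(fg)) {
      tab <- table(pred = pred[fg], truth = truth[fg])
      pa <- tabulate(pred[pred > 0L], nbins = max(pl))
      ta <- tabulate(truth[truth > 0L], nbins = max(tl))
      idx <- which(tab > 0, arr.ind = TRUE)
      if (nrow(idx) > 0L) {
        pv <- as.integer(rownames(tab))[idx[, 1]]
        tv <- as.integer(colnames(tab))[idx[, 2]]
        inter <- tab[idx]
        iou_v <- inter / (pa[pv] + ta[tv] - inter)
        cand <- data.frame(pred = pv, truth = tv, iou = as.numeric(iou_v))
        cand <- cand[cand$iou > tau, , drop = FALSE]
        cand <- cand[order(-cand$iou, cand$pred, cand$truth), , drop = FALSE]
        used_p <- logical(max(pl)); used_t <- logical(max(tl))
        for (i in seq_len(nrow(cand))) {
          p <- cand$pred[i]; t <- cand$truth[i]
          if (!used_p[p] && !used_t[t]) {
            used_p[p] <- TRUE; used_t[t] <- TRUE
            pairs <- rbind(pairs, cand[i, , drop = FALSE])
          }
        }
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tau = tau, TP = tp, FP = length(pl) - tp,
                 FN = length(tl) - tp, pairs = pairs),
            class = "cd_match")
}

#' Per-image average precision
#'
#' `AP = TP / (TP + FN + FP)` at the match's threshold. When the image has
#' no truth instances and nothing was predicted (all three counts zero) the
#' ratio is 0/0 and is defined as 1: an empty image, correctly left empty.
#'
#' @param match A `cd_match` from [match_instances()].
#' @return A fraction in `[0, 1]`.
#' @export
average_precision <- function(match) {
  stopifnot(inherits(match, "cd_match"))
  denom <- match$TP + match$FN + match$FP
  if (denom == 0L) return(1)
  match$TP / denom
}

#' Mean average precision over a test set
#'
#' Computes the per-image AP at each threshold and averages arithmetically
#' across images.
#'
#' @param preds,truths Equal-length lists of integer label maps.
#' @param taus IoU thresholds; default `c(0.5, 0.6, 0.7, 0.8, 0.9)`.
#' @return A data.frame with columns `tau`, `mean_ap`, and total `TP`,
#'   `FP`, `FN` over the set; per-image APs are attached as the
#'   `"per_image"` attribute (images x taus matrix).
#' @export
evaluate_set <- function(preds, truths, taus = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  if (length(preds) != length(truths))
    stop("pred list (", length(preds), ") and truth list (", length(truths),
         ") differ in length")
  ap <- matrix(NA_real_, length(preds), length(taus),
               dimnames = list(NULL, paste0("tau", taus)))
  tot <- matrix(0L, length(taus), 3L, dimnames = list(NULL, c("TP", "FP", "FN")))
  for (i in seq_along(preds)) {
    for (j in seq_along(taus)) {
      m <- match_instances(preds[[i]], truths[[i]], taus[j])
      ap[i, j] <- average_precision(m)
      tot[j, ] <- tot[j, ] + c(m$TP, m$FP, m$FN)
    }
  }
  out <- data.frame(tau = taus, mean_ap = colMeans(ap),
                    TP = tot[, "TP"], FP = tot[, "FP"], FN = tot[, "FN"])
  attr(out, "per_image") <- ap
  out
}
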