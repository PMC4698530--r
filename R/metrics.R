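# Quantitative evaluation of a segmentation against ground truth.

#' Evaluate a segmentation against a ground-truth label map
#'
#' Computes the N x N confusion matrix (rows = truth, columns = predicted)
#' over the foreground mask plus, for every class one-vs-rest: Dice
#' coefficient `2 TP / (2 TP + FP + FN)`, Jaccard index
#' `TP / (TP + FP + FN)`, detection probability `TP / (TP + FN)` and
#' false-alarm probability `FP / (FP + TN)`. Background voxels are
#' excluded. Rates that are undefined (class absent from truth, or from
#' both truth and prediction) are reported as `NA`, never silently as 0
#' or 1.
#'
#' @param seg A [segmentation] whose foreground labels lie in 1..N.
#' @param truth A [label_map] with N classes.
#' @param mask Logical matrix; default: truth foreground.
#' @return An object of class `evaluation_report`: list with `confusion`,
#'   `per_class` (data frame of the four rates per class),
#'   `overall_accuracy` and `n_voxels`.
#' @export
evaluate_segmentation <- function(seg, truth, mask = NULL) {
  stopifnot(inherits(seg, "segmentation"), inherits(truth, "label_map"))
  tl <- truth$labels
  if (!all(dim(seg$labels) == dim(tl))) stop("shape mismatch")
  if (is.null(mask)) mask <- tl > 0L
  if (!any(mask)) stop("empty evaluation mask")
  n <- length(truth$class_names)
  t_v <- tl[mask]
  p_v <- seg$labels[mask]
  if (any(p_v < 0L) || any(p_v > n) || any(t_v < 1L) || any(t_v > n))
    stop("labels outside 0..", n, " on the mask")
  if (any(p_v == 0L))
    stop(sum(p_v == 0L), " masked voxel(s) left unclassified")
  conf <- matrix(0L, n, n, dimnames = list(truth = truth$class_names,
                                           predicted = truth$class_names))
  tab <- table(factor(t_v, levels = seq_len(n)),
               factor(p_v, levels = seq_len(n)))
  conf[] <- as.integer(tab)
  nv <- length(t_v)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  tn <- nv - tp - fn - fp
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  dice <- rate(2 * tp, 2 * tp + fp + fn)
  jac <- rate(tp, tp + fp + fn)
  pd <- rate(tp, tp + fn)
  pfa <- rate(fp, fp + tn)
  per <- data.frame(class = seq_len(n), name = truth$class_names,
                    dice = dice, jaccard = jac,
                    detection_probability = pd,
                    false_alarm_probability = pfa,
                    truth_voxels = as.integer(rowSums(conf)),
                    row.names = NULL)
  structure(list(confusion = conf, per_class = per,
                 overall_accuracy = sum(tp) / nv, n_voxels = nv),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("<evaluation_report> %d voxels, overall accuracy %.4f\n",
              x$n_voxels, x$overall_accuracy))
  print(format(x$per_class, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Align arbitrary cluster indices with truth classes
#'
#' Unsupervised clusterings (K-means in particular) return arbitrary
#' cluster indices. This finds the one-to-one assignment of predicted
#' clusters to truth classes that maximises the total overlap (sum of
#' matched confusion counts) by exhaustive search over permutations —
#' exact, and cheap for the handful of tissue classes considered here —
#' and returns the relabeled segmentation.
#'
#' @param seg A [segmentation] with foreground labels 1..N.
#' @param truth A [label_map] with the same number of classes (N <= 8).
#' @return The relabeled [segmentation] (metrics planes permuted to
#'   match).
#' @export
match_labels <- function(seg, truth) {
  stopifnot(inherits(seg, "segmentation"), inherits(truth, "label_map"))
  n <- length(truth$class_names)
  segn <- max(seg$labels)
  if (segn != n)
    stop(sprintf("segmentation has %d classes but truth has %d", segn, n))
  if (n > 8L) stop("exhaustive matching supports at most 8 classes")
  mask <- truth$labels > 0L & seg$labels > 0L
  conf <- table(factor(truth$labels[mask], levels = seq_len(n)),
                factor(seg$labels[mask], levels = seq_len(n)))
  perms <- permutations(n)
  overlap <- apply(perms, 1, function(p) sum(conf[cbind(p, seq_len(n))]))
  best <- perms[which.max(overlap), ]  # best[j] = truth class for cluster j
  lab <- seg$labels
  fg <- lab > 0L
  lab[fg] <- best[lab[fg]]
  met <- seg$metrics
  if (!is.null(met)) met <- met[, , order(best), drop = FALSE]
  segmentation(lab, met, seg$criterion)
}

#' Isolated single-voxel segmentation errors
#'
#' Indices of misclassified foreground voxels none of whose in-mask
#' 8-neighbors share the voxel's predicted label — the "salt" errors that
#' a spatial regularizer is designed to remove.
#'
#' @param seg A [segmentation].
#' @param truth A [label_map].
#' @return Integer vector of voxel indices (into the label matrix).
#' @export
isolated_errors <- function(seg, truth) {
  stopifnot(inherits(seg, "segmentation"), inherits(truth, "label_map"))
  lab <- seg$labels
  mask <- truth$labels > 0L & lab > 0L
  n <- max(lab)
  nb <- neighbor_label_counts(lab, mask, n)
  idx <- which(mask & lab != truth$labels)
  own <- vapply(idx, function(i) {
    k <- lab[i]
    nb$counts[, , k][i]
  }, numeric(1))
  idx[own == 0]
}

# all permutations of 1..n as rows
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
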