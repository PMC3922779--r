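# Precision/recall scoring of segmentation masks against expert (or
# synthetic) cell-center ground truth, and the paired strategy comparison
# harness.

#' Match segmented objects against ground-truth cell centers
#'
#' Center-in-object matching: a labeled object containing at least one
#' center is one true positive; each additional center inside an
#' already-matched object counts one false negative (cells merged into one
#' object); objects containing no center are false positives; centers in
#' background are false negatives. Two identities always hold:
#' `tp + fn == nrow(centers)` and `tp + fp == number of objects`.
#'
#' @param mask Integer label mask.
#' @param centers Data frame with columns `x` (pixel column) and `y` (pixel
#'   row), 1-based, inside the mask bounds.
#' @return Object of class `"detection_counts"`: list with `tp`, `fp`,
#'   `fn`, `precision`, `recall` (ratios are `NA` when their denominator
#'   is 0).
#' @export
match_detections <- function(mask, centers) {
  validate_label_mask(mask)
  n_objects <- max(0L, max(mask))
  if (nrow(centers) > 0) {
    x <- round(centers$x); y <- round(centers$y)
    if (any(x < 1) || any(y < 1) || any(x > ncol(mask)) || any(y > nrow(mask)))
      stop("center out of mask bounds")
    hit <- mask[cbind(y, x)]
    tp <- length(unique(hit[hit > 0L]))
    fn <- sum(hit == 0L) + (sum(hit > 0L) - tp)
  } else {
    tp <- 0L; fn <- 0L
  }
  fp <- n_objects - tp
  detection_counts(tp, fp, fn)
}

#' Construct detection counts
#' @param tp,fp,fn Non-negative integer counts of true positive, false
#'   positive and false negative objects.
#' @return Object of class `"detection_counts"`.
#' @export
detection_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  pr <- precision_recall_values(tp, fp, fn)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 precision = pr[["precision"]], recall = pr[["recall"]]),
            class = "detection_counts")
}

precision_recall_values <- function(tp, fp, fn) {
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Precision and recall from detection counts
#'
#' `Pr = tp/(tp + fp)`, `Re = tp/(tp + fn)`; an undefined ratio (zero
#' denominator) is reported as `NA`, never silently as 0 or 1.
#'
#' @param counts A [detection_counts()].
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  precision_recall_values(counts$tp, counts$fp, counts$fn)
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf("<detection_counts tp=%d fp=%d fn=%d precision=%s recall=%s>\n",
              x$tp, x$fp, x$fn,
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              ifelse(is.na(x$recall), "NA", sprintf("%.3f", x$recall))))
  invisible(x)
}

#' Compare the adaptive and fixed frame-selection strategies end to end
#'
#' For each simulated stack, selects frames with both strategies (sharing
#' one NCD matrix per stack), segments with both quads, and scores each
#' mask against the ground-truth centers. A stack whose processing fails is
#' skipped with a warning and counted.
#'
#' @param sims List of simulations as returned by [generate_zstack()]
#'   (each has `stack` and `truth`).
#' @param params [seg_params()] used for both strategies.
#' @param weak_um,strong_um Offsets of the fixed baseline.
#' @param bins Histogram bins for focus detection.
#' @return Object of class `"strategy_comparison"`: list with `per_stack`
#'   (one row per stack: Psi and tp/fp/fn/precision/recall per strategy),
#'   `summary` (means and the fraction of stacks with
#'   `psi_maxinfo >= psi_fixed`), and `n_skipped`.
#' @export
compare_strategies <- function(sims, params = seg_params(),
                               weak_um = 10, strong_um = 25, bins = 256L) {
  stopifnot(length(sims) >= 1L)
  rows <- list()
  n_skipped <- 0L
  for (sim in sims) {
    res <- tryCatch({
      stack <- sim$stack
      enc <- frame_encodings(stack)
      D <- ncd_matrix(enc)
      q_max <- select_frames_maxinfo(stack, bins = bins,
                                     encodings = enc, D = D)
      q_fix <- select_frames_fixed(stack, weak_um = weak_um,
                                   strong_um = strong_um, bins = bins,
                                   encodings = enc, D = D)
      m_max <- segment_stack(stack, q_max, params)
      m_fix <- segment_stack(stack, q_fix, params)
      c_max <- match_detections(m_max, sim$truth$centers)
      c_fix <- match_detections(m_fix, sim$truth$centers)
      data.frame(
        stack_id = stack$stack_id,
        n_cells = nrow(sim$truth$centers),
        psi_maxinfo = q_max$psi, psi_fixed = q_fix$psi,
        tp_maxinfo = c_max$tp, fp_maxinfo = c_max$fp, fn_maxinfo = c_max$fn,
        precision_maxinfo = c_max$precision, recall_maxinfo = c_max$recall,
        tp_fixed = c_fix$tp, fp_fixed = c_fix$fp, fn_fixed = c_fix$fn,
        precision_fixed = c_fix$precision, recall_fixed = c_fix$recall)
    }, error = function(e) {
      warning("skipping stack '", sim$stack$stack_id, "': ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_skipped <- n_skipped + 1L else rows[[length(rows) + 1L]] <- res
  }
  per_stack <- do.call(rbind, rows)
  summary <- if (!is.null(per_stack) && nrow(per_stack) > 0) {
    list(
      n_stacks = nrow(per_stack),
      mean_psi_maxinfo = mean(per_stack$psi_maxinfo),
      mean_psi_fixed = mean(per_stack$psi_fixed),
      psi_dominance_fraction =
        mean(per_stack$psi_maxinfo >= per_stack$psi_fixed),
      mean_precision_maxinfo = mean(per_stack$precision_maxinfo, na.rm = TRUE),
      mean_precision_fixed = mean(per_stack$precision_fixed, na.rm = TRUE),
      mean_recall_maxinfo = mean(per_stack$recall_maxinfo, na.rm = TRUE),
      mean_recall_fixed = mean(per_stack$recall_fixed, na.rm = TRUE))
  } else list(n_stacks = 0L)
  structure(list(per_stack = per_stack, summary = summary,
                 n_skipped = n_skipped),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  s <- x$summary
  cat("<strategy_comparison>\n")
  if (s$n_stacks == 0L) {
    cat("  no stacks processed (", x$n_skipped, " skipped)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  stacks: %d (%d skipped)\n", s$n_stacks, x$n_skipped))
  cat(sprintf("  mean psi      maxinfo %.2f | fixed %.2f (dominance %.0f%%)\n",
              s$mean_psi_maxinfo, s$mean_psi_fixed,
              100 * s$psi_dominance_fraction))
  cat(sprintf("  mean precision maxinfo %.3f | fixed %.3f\n",
              s$mean_precision_maxinfo, s$mean_precision_fixed))
  cat(sprintf("  mean recall    maxinfo %.3f | fixed %.3f\n",
              s$mean_recall_maxinfo, s$mean_recall_fixed))
  invisible(x)
}
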