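# Training loss (binary cross-entropy + Dice, equally weighted) and the
# Dice-based evaluation machinery: per-case volume DSC in percent,
# performance gain versus a baseline, and ablation mean +/- SD summaries.

#' @keywords internal
check_pair <- function(y, y_hat, soft = TRUE) {
  if (!identical(dim(y) %||% length(y), dim(y_hat) %||% length(y_hat))) {
    stop("ground truth and prediction shapes differ", call. = FALSE)
  }
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (!length(y)) stop("empty label pair", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("ground truth must be binary (0/1)", call. = FALSE)
  if (min(y_hat) < 0 || max(y_hat) > 1) {
    stop("predictions must lie in [0, 1]", call. = FALSE)
  }
  if (!soft && !all(y_hat %in% c(0, 1))) {
    stop("predictions must be binary for evaluation", call. = FALSE)
  }
  list(y = y, y_hat = y_hat)
}

#' Binary cross-entropy loss
#'
#' `-(1/n) * sum(y * log(p) + (1 - y) * log(1 - p))` with predictions clamped
#' to `[eps, 1 - eps]` before the logarithms so saturated predictions give a
#' finite loss.
#'
#' @param y binary ground-truth labels (vector, matrix or array).
#' @param y_hat predicted probabilities in `[0, 1]`, same shape.
#' @param eps clamping constant (default `1e-7`).
#' @return non-negative scalar; ~0 iff the prediction equals the labels.
#' @examples
#' bce_loss(1, 0.5)  # log(2)
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  p <- check_pair(y, y_hat)
  ph <- clamp(p$y_hat, eps, 1 - eps)
  -mean(p$y * log(ph) + (1 - p$y) * log(1 - ph))
}

#' Dice similarity coefficient
#'
#' Sum form `2 * sum(y * p) / (sum(y) + sum(p))`, valid for soft predictions
#' (used as a loss) and binary ones (used as the evaluation metric, where it
#' equals `2|A n B| / (|A| + |B|)`). Symmetric; `dsc(y, y) = 1`. When both
#' masks are empty the value is 1 by convention (perfect agreement on
#' absence), with a message so users can audit.
#'
#' @param y binary ground truth.
#' @param y_hat prediction in `[0, 1]`, same shape.
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(y, y_hat) {
  p <- check_pair(y, y_hat)
  denom <- sum(p$y) + sum(p$y_hat)
  if (denom == 0) {
    message("dsc: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(p$y * p$y_hat) / denom
}

#' Dice loss: `1 - dsc`
#' @inheritParams dsc
#' @return scalar in `[0, 1]`.
#' @export
dsc_loss <- function(y, y_hat) 1 - dsc(y, y_hat)

#' Combined loss: `0.5 * BCE + 0.5 * Dice loss`
#' @inheritParams bce_loss
#' @return non-negative scalar, ~0 only at (near-)perfect prediction.
#' @examples
#' combined_loss(1, 0.5)  # 0.5 * log(2) + 0.5 * (1 - 2*0.5/1.5)
#' @export
combined_loss <- function(y, y_hat, eps = 1e-7) {
  0.5 * bce_loss(y, y_hat, eps) + 0.5 * dsc_loss(y, y_hat)
}

#' Evaluate a segmented case: volume-level DSC in percent
#'
#' One number per case, computed over all voxels of the 3D volume at once
#' (not slice-averaged), as in per-case reporting of airway segmentation
#' performance.
#'
#' @param pred_mask binary predicted volume (array or `is_volume`).
#' @param gt_mask binary ground-truth volume, same shape.
#' @return DSC as a percentage in `[0, 100]`.
#' @export
evaluate_case <- function(pred_mask, gt_mask) {
  pred <- volume_data(pred_mask)
  gt <- volume_data(gt_mask)
  if (!identical(dim(pred), dim(gt))) {
    stop("prediction and ground-truth shapes differ", call. = FALSE)
  }
  100 * dsc(as.numeric(gt), as.numeric(pred))
}

#' Performance gain in percentage points
#'
#' `dsc_method - dsc_baseline`; may be negative.
#'
#' @param dsc_method,dsc_baseline DSC values in percent, in `[0, 100]`.
#' @return difference in percentage points.
#' @export
performance_gain <- function(dsc_method, dsc_baseline) {
  if (any(c(dsc_method, dsc_baseline) < 0) || any(c(dsc_method, dsc_baseline) > 100)) {
    stop("DSC values must lie in [0, 100]", call. = FALSE)
  }
  dsc_method - dsc_baseline
}

#' Ablation summary: mean +/- SD of per-case DSC per configuration
#'
#' @param per_case_dsc data frame with one row per case; a `case` column is
#'   ignored, every other selected column is a configuration of aggregated
#'   interpolation ratios.
#' @param configs which configuration columns to summarise (default: all
#'   non-`case` columns, in the given order, e.g. smallest to largest subset).
#' @return data frame with columns `configuration`, `n`, `mean`, `sd`
#'   (sample SD, n - 1 denominator; `NA` for a single case).
#' @export
ablation_summary <- function(per_case_dsc,
                             configs = setdiff(names(per_case_dsc), "case")) {
  if (!is.data.frame(per_case_dsc) || !nrow(per_case_dsc) || !length(configs)) {
    stop("empty ablation table", call. = FALSE)
  }
  missing_cols <- setdiff(configs, names(per_case_dsc))
  if (length(missing_cols)) {
    stop("unknown configuration column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    configuration = configs,
    n = vapply(configs, function(cc) sum(!is.na(per_case_dsc[[cc]])), integer(1)),
    mean = vapply(configs, function(cc) mean(per_case_dsc[[cc]], na.rm = TRUE), numeric(1)),
    sd = vapply(configs, function(cc) {
      v <- per_case_dsc[[cc]][!is.na(per_case_dsc[[cc]])]
      if (length(v) < 2) NA_real_ else stats::sd(v)
    }, numeric(1)),
    row.names = NULL
  )
}
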