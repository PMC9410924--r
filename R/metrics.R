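#' Mean squared error between two images
#'
#' `MSE = (1 / (h l)) sum (f(a,b) - fhat(a,b))^2`.
#'
#' @param reference Reference (noise-free) image.
#' @param test Image under test.
#' @return MSE in squared intensity units.
#' @export
mse <- function(reference, test) {
  check_same_shape(reference, test)
  mean((reference - test)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(pe_max^2 / MSE)` in dB; `+Inf` when the images are
#' identical.
#'
#' @param reference Reference image.
#' @param test Image under test.
#' @param pe_max Peak intensity value (1 for `[0, 1]` floats, 255 for
#'   8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, pe_max = 1.0) {
  if (pe_max <= 0) stop("pe_max must be > 0", call. = FALSE)
  e <- mse(reference, test)
  if (e == 0) return(Inf)
  10 * log10(pe_max^2 / e)
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred Predicted 0/1 mask.
#' @param truth Ground-truth 0/1 mask.
#' @return Named numeric vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- validate_binary_mask(pred, "pred")
  truth <- validate_binary_mask(truth, "truth")
  check_same_shape(pred, truth, "masks")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  tn <- sum(pred == 0L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 tp / (2 tp + fp + fn)`; 1 when both masks are empty.
#'
#' @inheritParams confusion_counts
#' @return Value in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  ct <- confusion_counts(pred, truth)
  den <- 2 * ct[["tp"]] + ct[["fp"]] + ct[["fn"]]
  if (den == 0) return(1)
  2 * ct[["tp"]] / den
}

#' Matthews correlation coefficient
#'
#' `MCC = (tp tn - fp fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with 0
#' returned when any factor of the denominator vanishes (the standard
#' convention).
#'
#' @inheritParams confusion_counts
#' @return Value in `[-1, 1]`.
#' @export
matthews_cc <- function(pred, truth) {
  ct <- as.double(confusion_counts(pred, truth))
  names(ct) <- c("tp", "fp", "tn", "fn")
  den2 <- (ct["tp"] + ct["fp"]) * (ct["tp"] + ct["fn"]) *
    (ct["tn"] + ct["fp"]) * (ct["tn"] + ct["fn"])
  if (den2 == 0) return(0)
  unname((ct["tp"] * ct["tn"] - ct["fp"] * ct["fn"]) / sqrt(den2))
}

#' Pixel error rate of a segmentation
#'
#' Misclassified-pixel fraction. With `normalize = "frame"` (default) the
#' denominator is the whole frame, `(fp + fn) / (tp + fp + tn + fn)`; with
#' `"foreground"` it is the truth foreground area, `(fp + fn) / (tp + fn)`.
#'
#' @inheritParams confusion_counts
#' @param normalize Denominator convention.
#' @return Error fraction (>= 0; can exceed 1 under `"foreground"`).
#' @export
pixel_error_rate <- function(pred, truth,
                             normalize = c("frame", "foreground")) {
  normalize <- match.arg(normalize)
  ct <- confusion_counts(pred, truth)
  den <- switch(normalize,
                frame = sum(ct),
                foreground = ct[["tp"]] + ct[["fn"]])
  if (den == 0) return(0)
  (ct[["fp"]] + ct[["fn"]]) / den
}

#' Full segmentation / denoising report
#'
#' Bundles DSC, MCC, pixel error rate and the confusion counts for a mask
#' pair, optionally adding PSNR and MSE when a clean reference and a
#' processed image are supplied.
#'
#' @inheritParams confusion_counts
#' @param reference,processed Optional images for PSNR/MSE.
#' @param pe_max Peak value for PSNR.
#' @return A list of class `metrics_report` with keys `dsc`, `mcc`,
#'   `error_rate`, `tp`, `fp`, `tn`, `fn` and, when images are given,
#'   `psnr`, `mse`.
#' @export
metrics_report <- function(pred, truth, reference = NULL, processed = NULL,
                           pe_max = 1.0) {
  ct <- confusion_counts(pred, truth)
  rep <- list(dsc = dice_coefficient(pred, truth),
              mcc = matthews_cc(pred, truth),
              error_rate = pixel_error_rate(pred, truth),
              tp = ct[["tp"]], fp = ct[["fp"]], tn = ct[["tn"]],
              fn = ct[["fn"]])
  if (!is.null(reference) && !is.null(processed)) {
    rep$psnr <- psnr(reference, processed, pe_max)
    rep$mse <- mse(reference, processed)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("DSC %.4f  MCC %.4f  error rate %.4f", x$dsc, x$mcc,
              x$error_rate))
  if (!is.null(x$psnr)) cat(sprintf("  PSNR %.2f dB  MSE %.3g", x$psnr, x$mse))
  cat("\n")
  invisible(x)
}
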