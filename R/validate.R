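#' Paired device/reference blood-pressure series
#'
#' @param device,reference Paired per-beat pressures (mmHg), equal length
#'   >= 2, no missing values.
#' @param label `"SBP"` or `"DBP"` (or any descriptive label).
#' @return An object of class `paired_bp_series`.
#' @export
paired_bp_series <- function(device, reference, label = "SBP") {
  if (length(device) != length(reference)) {
    stop("`device` and `reference` must have equal length", call. = FALSE)
  }
  if (length(device) < 2) stop("need at least two paired beats", call. = FALSE)
  if (anyNA(device) || anyNA(reference)) {
    stop("missing values are not allowed after pairing", call. = FALSE)
  }
  structure(list(device = as.numeric(device), reference = as.numeric(reference),
                 label = label),
            class = "paired_bp_series")
}

#' Device-against-reference agreement statistics
#'
#' Computes the validation statistics used for cuffless BP devices: mean
#' absolute error and its SD, Pearson correlation, and Bland-Altman bias with
#' 95% limits of agreement (bias +/- 1.96 times the SD of the differences).
#' All SDs use the n-1 denominator. The "+/- SD" attached to the MAE is the
#' sample SD of the absolute differences.
#'
#' @param paired A [paired_bp_series()], or the device vector when
#'   `reference` is also given.
#' @param reference Optional reference vector (with `paired` as device).
#' @param label Series label when building from two vectors.
#' @return An `agreement_stats`: `mae`, `mae_sd`, `pearson_r`, `bias`,
#'   `diff_sd`, `loa_low`, `loa_high`, `n`. `pearson_r` is `NA` (with a
#'   warning) when either series has zero variance.
#' @examples
#' agreement(c(120, 125, 130), c(121, 124, 132))
#' @export
agreement <- function(paired, reference = NULL, label = "SBP") {
  if (!inherits(paired, "paired_bp_series")) {
    paired <- paired_bp_series(paired, reference, label)
  }
  d <- paired$device - paired$reference
  ad <- abs(d)
  diff_sd <- stats::sd(d)
  r <- if (stats::sd(paired$device) == 0 || stats::sd(paired$reference) == 0) {
    warning("zero variance in a series; Pearson r undefined")
    NA_real_
  } else {
    stats::cor(paired$device, paired$reference)
  }
  bias <- mean(d)
  structure(
    list(label = paired$label,
         mae = mean(ad), mae_sd = stats::sd(ad),
         pearson_r = r,
         bias = bias, diff_sd = diff_sd,
         loa_low = bias - 1.96 * diff_sd,
         loa_high = bias + 1.96 * diff_sd,
         n = length(d)),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("%s agreement (n = %d):\n", x$label, x$n))
  cat(sprintf("  MAE %.2f +/- %.2f mmHg\n", x$mae, x$mae_sd))
  cat(sprintf("  Pearson r = %s\n",
              if (is.na(x$pearson_r)) "undefined" else sprintf("%.3f", x$pearson_r)))
  cat(sprintf("  Bland-Altman bias %.3f mmHg (SD %.2f), 95%% LoA [%.2f, %.2f]\n",
              x$bias, x$diff_sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot data
#'
#' Per-beat mean and difference, ready for a mean-difference plot.
#'
#' @param paired A [paired_bp_series()].
#' @return Data frame with `mean_mmHg` and `difference_mmHg`.
#' @export
bland_altman_data <- function(paired) {
  stopifnot(inherits(paired, "paired_bp_series"))
  data.frame(mean_mmHg = (paired$device + paired$reference) / 2,
             difference_mmHg = paired$device - paired$reference)
}

#' British Hypertension Society accuracy grade
#'
#' Grades a device by the cumulative percentage of absolute errors within 5,
#' 10 and 15 mmHg: grade A requires at least 60/85/95%, B 50/75/90%,
#' C 40/65/85%; anything less is D.
#'
#' @param differences Device-minus-reference errors (mmHg), n >= 1.
#' @return A `bhs_grade`: `within_5`, `within_10`, `within_15` (percent),
#'   `grade`, `n`.
#' @export
bhs_grade <- function(differences) {
  if (length(differences) < 1) stop("need at least one difference", call. = FALSE)
  ad <- abs(differences)
  pct <- function(th) 100 * mean(ad <= th)
  p <- c(within_5 = pct(5), within_10 = pct(10), within_15 = pct(15))
  tiers <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  grade <- "D"
  for (g in names(tiers)) {
    if (all(p >= tiers[[g]])) { grade <- g; break }
  }
  structure(list(within_5 = unname(p[1]), within_10 = unname(p[2]),
                 within_15 = unname(p[3]), grade = grade,
                 n = length(differences)),
            class = "bhs_grade")
}

#' @export
print.bhs_grade <- function(x, ...) {
  cat(sprintf(
    "BHS grade %s (n = %d): %.1f%% within 5, %.1f%% within 10, %.1f%% within 15 mmHg\n",
    x$grade, x$n, x$within_5, x$within_10, x$within_15))
  invisible(x)
}

#' AAMI accuracy criterion
#'
#' Pass requires the mean error within +/- 5 mmHg and the error SD at most
#' 8 mmHg.
#'
#' @param differences Device-minus-reference errors (mmHg), n >= 2.
#' @return An `aami_check`: `mean_error`, `sd_error`, `pass`, `n`.
#' @export
aami_check <- function(differences) {
  if (length(differences) < 2) stop("need at least two differences", call. = FALSE)
  m <- mean(differences)
  s <- stats::sd(differences)
  structure(list(mean_error = m, sd_error = s,
                 pass = abs(m) <= 5 && s <= 8, n = length(differences)),
            class = "aami_check")
}

#' @export
print.aami_check <- function(x, ...) {
  cat(sprintf("AAMI criterion: %s (mean error %.2f mmHg, SD %.2f mmHg, n = %d)\n",
              if (x$pass) "PASS" else "FAIL", x$mean_error, x$sd_error, x$n))
  invisible(x)
}
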