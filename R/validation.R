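#' Model performance metrics
#'
#' The validation statistics comparing predicted with measured
#' concentrations: the coefficient of determination `r2` and two-sided `p`
#' of the least-squares regression of measured on predicted, the mean
#' absolute error `MAE = mean(|pred - meas|)` and the root mean square
#' error `RMSE = sqrt(mean((pred - meas)^2))`. All on the arithmetic
#' concentration scale. `RMSE >= MAE` always, with equality iff all
#' absolute errors are equal.
#'
#' @param predicted Predicted concentrations, ug/g ww.
#' @param measured Measured concentrations, ug/g ww, same length.
#' @return A list of class `performance_metrics`: `r2`, `p_value`, `mae`,
#'   `rmse`, `n`. With fewer than 3 points or zero variance in the
#'   predictions, `r2`/`p_value` are `NA` (with a warning) while
#'   MAE/RMSE are still returned.
#' @export
#' @examples
#' performance_metrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
performance_metrics <- function(predicted, measured) {
  predicted <- as.numeric(predicted); measured <- as.numeric(measured)
  n <- length(predicted)
  if (n < 1L || length(measured) != n)
    stop("need equal-length predicted and measured vectors (n >= 1)")
  err <- predicted - measured
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  r2 <- NA_real_; p <- NA_real_
  if (n >= 3L) {
    if (stats::var(predicted) == 0) {
      warning("undefined r2: zero variance in predictions; ",
              "MAE/RMSE still returned")
    } else {
      # a perfect fit is a legitimate input here (noise-free validation);
      # silence summary.lm's "essentially perfect fit" caution only
      fit <- withCallingHandlers(
        summary(stats::lm(measured ~ predicted)),
        warning = function(w) {
          if (grepl("essentially perfect fit", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      r2 <- fit$r.squared
      p <- unname(fit$coefficients[2, 4])
    }
  }
  structure(list(r2 = r2, p_value = p, mae = mae, rmse = rmse, n = n),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  cat(sprintf("Performance (n = %d): r2 = %s, p = %s, MAE = %.4g, RMSE = %.4g\n",
              x$n,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2),
              if (is.na(x$p_value)) "NA" else sprintf("%.3g", x$p_value),
              x$mae, x$rmse))
  invisible(x)
}

#' Bioconcentration factor (parasite/host)
#'
#' Per-subject ratio of the parasite concentration to the host
#' concentration, summarised as arithmetic mean and sample standard
#' deviation (n - 1 denominator).
#'
#' @param parasite_conc Per-subject parasite concentrations, ug/g ww.
#' @param host_conc Per-subject host concentrations, ug/g ww, paired.
#' @return A list of class `bcf_summary`: `mean`, `sd` (`NA` for a single
#'   usable pair), `n`, `ratios`.
#' @export
#' @examples
#' bioconcentration_factor(c(10, 10), c(2, 2))   # 5 +/- 0
bioconcentration_factor <- function(parasite_conc, host_conc) {
  parasite_conc <- as.numeric(parasite_conc)
  host_conc <- as.numeric(host_conc)
  if (length(parasite_conc) != length(host_conc) || length(host_conc) < 1L)
    stop("need paired per-subject parasite and host concentrations")
  ok <- is.finite(host_conc) & host_conc > 0 & is.finite(parasite_conc)
  if (any(!ok))
    warning(sum(!ok), " pair(s) with nonpositive or missing host ",
            "concentration excluded")
  if (!any(ok)) stop("no usable pairs")
  ratios <- parasite_conc[ok] / host_conc[ok]
  structure(list(
    mean = mean(ratios),
    sd = if (length(ratios) >= 2L) stats::sd(ratios) else NA_real_,
    n = length(ratios),
    ratios = ratios
  ), class = "bcf_summary")
}

#' @export
print.bcf_summary <- function(x, ...) {
  cat(sprintf("Bioconcentration factor: %.4g (+/- %s), n = %d\n",
              x$mean, if (is.na(x$sd)) "NA" else sprintf("%.4g", x$sd), x$n))
  invisible(x)
}

#' Read paired predicted/measured observations from CSV
#'
#' @param path CSV with columns `predicted`, `measured` and optionally
#'   `compartment`, `metal`, `group`, `measured_sd`.
#' @return A data frame.
#' @export
read_paired_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("predicted", "measured") %in% names(df)))
    stop("schema error in ", path,
         ": need columns 'predicted' and 'measured'")
  df
}
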