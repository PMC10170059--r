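#' Fit the linear log2(TPM) to Ct calibration
#'
#' Ordinary least squares of Ct on log2(TPM): Ct = b0 + b1 * log2(TPM).
#' Because higher expression crosses the fluorescence threshold earlier,
#' the slope is expected to be negative. The slope p-value is the F-test of
#' the regression on (1, n - 2) degrees of freedom, identical to the
#' two-sided t-test in simple regression, and R^2 equals the squared
#' Pearson correlation of the two variables.
#'
#' @param pairs Data frame with columns `log2tpm` and `ct` (extra columns
#'   ignored), n >= 3 rows, `log2tpm` not all identical.
#' @return An object of class `ref_ctfit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, and the underlying [stats::lm] fit.
#' @export
fit_tpm_ct <- function(pairs) {
  if (!all(c("log2tpm", "ct") %in% names(pairs))) {
    abort("`pairs` needs columns log2tpm and ct")
  }
  pairs <- dplyr::filter(pairs, is.finite(.data$log2tpm), is.finite(.data$ct))
  if (nrow(pairs) < 3) abort("need at least 3 complete (log2tpm, ct) pairs")
  if (sd(pairs$log2tpm) == 0) abort("log2tpm values are all identical")
  fit <- stats::lm(ct ~ log2tpm, data = pairs)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(
    slope = unname(stats::coef(fit)["log2tpm"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    p_value = p,
    n = nrow(pairs),
    lm_fit = fit
  ), class = "ref_ctfit")
}

#' Predict a Ct value from a TPM value
#'
#' @param fit A `ref_ctfit` object from [fit_tpm_ct()], or any list with
#'   `slope` and `intercept`.
#' @param tpm TPM value(s), strictly positive.
#' @return Predicted Ct, `intercept + slope * log2(tpm)`.
#' @export
predict_ct <- function(fit, tpm) {
  if (any(!is.finite(tpm) | tpm <= 0)) abort("tpm must be finite and > 0")
  fit$intercept + fit$slope * log2(tpm)
}

#' @export
print.ref_ctfit <- function(x, ...) {
  cat(sprintf("Ct = %.4f * log2(TPM) + %.2f   (R^2 = %.4f, p = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @rdname fit_tpm_ct
#' @param x A `ref_ctfit` object.
#' @param ... Unused.
#' @export
tidy.ref_ctfit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "log2tpm"),
                 estimate = c(x$intercept, x$slope)) |>
    dplyr::left_join(
      tibble::as_tibble(summary(x$lm_fit)$coefficients, rownames = "term") |>
        dplyr::select("term", std.error = "Std. Error",
                      statistic = "t value", p.value = "Pr(>|t|)"),
      by = "term")
}

#' @rdname fit_tpm_ct
#' @export
glance.ref_ctfit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n,
                 sigma = summary(x$lm_fit)$sigma)
}
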