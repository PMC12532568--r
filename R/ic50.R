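#' Four-parameter logistic (4PL) inhibition fit
#'
#' Fits `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)` by
#' least squares on log-dose, the standard model for inhibition titrations
#' (responses normalized so vehicle is about 1, falling toward `bottom` at
#' high dose; `hill > 0`). Initialization is a fixed, deterministic rule:
#' `top`/`bottom` from the response extremes, `ic50` from the geometric
#' mean of the doses bracketing the half-response, `hill = 1`.
#'
#' Flat data (response span below `no_transition_span`) raise a
#' `"lc3_no_transition"` condition; non-convergence raises
#' `"lc3_fit_error"` with the optimizer diagnostics.
#'
#' @param doses Positive concentrations (uM); at least 4 levels.
#' @param responses Normalized responses, same length.
#' @param no_transition_span Minimum response span treated as a real
#'   transition (default 0.1 in normalized units).
#' @return Object of class `lc3_ic50_fit` with elements `bottom, top, ic50,
#'   hill`, the underlying `nls` fit, and the data. Methods: [tidy()],
#'   [glance()], [autoplot()], `predict()`.
#' @export
#' @examples
#' d <- c(10, 30, 60, 100, 180, 300, 600, 1000)
#' y <- 1 / (1 + (d / 100))
#' fit <- fit_ic50(d, y)
#' fit$ic50
fit_ic50 <- function(doses, responses, no_transition_span = 0.1) {
  ok <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 4) {
    abort("need >= 4 positive dose levels", class = "lc3_usage_error")
  }
  span <- diff(range(responses))
  if (span < no_transition_span) {
    abort("no transition: response span below threshold",
          class = "lc3_no_transition", span = span)
  }
  # deterministic initialization
  top0 <- max(responses); bottom0 <- min(responses)
  half <- (top0 + bottom0) / 2
  ord <- order(doses)
  ds <- doses[ord]; rs <- responses[ord]
  below <- which(rs <= half)
  ic50_0 <- if (length(below) == 0 || below[1] == 1) {
    exp(mean(log(range(ds))))
  } else {
    exp(mean(log(c(ds[below[1] - 1], ds[below[1]]))))
  }
  df <- tibble(dose = doses, response = responses)
  model <- function(p, dose) {
    p["bottom"] + (p["top"] - p["bottom"]) /
      (1 + exp(p["hill"] * (log(dose) - p["log_ic50"])))
  }
  # box constraints keep the optimizer off the degenerate 4PL ridge
  # (hill -> 0 with top/bottom running to +-Inf at finite deviance)
  rspan <- span
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(bottom = bottom0, top = top0, log_ic50 = log(ic50_0),
              hill = 1),
      fn = function(p) df$response - model(p, df$dose),
      lower = c(bottom = bottom0 - rspan, top = bottom0,
                log_ic50 = log(min(doses)) - 2.3, hill = 0.05),
      upper = c(bottom = top0, top = top0 + rspan,
                log_ic50 = log(max(doses)) + 2.3, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 10000,
                                           ftol = 1e-10, ptol = 1e-10)
    ),
    error = function(e) abort(paste0("4PL fit did not converge: ",
                                     conditionMessage(e)),
                              class = "lc3_fit_error")
  )
  if (!fit$info %in% 1:4) {
    abort(paste0("4PL fit did not converge: ", fit$message),
          class = "lc3_fit_error")
  }
  cf <- fit$par
  out <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
              ic50 = exp(unname(cf["log_ic50"])),
              hill = unname(cf["hill"]), fit = fit, data = df)
  if (out$bottom > out$top) {
    warn("fitted bottom exceeds top; curve is rising, check orientation")
  }
  class(out) <- "lc3_ic50_fit"
  out
}

#' @export
print.lc3_ic50_fit <- function(x, ...) {
  cat(sprintf(paste0("<lc3_ic50_fit> IC50 = %.4g uM, hill = %.3g, ",
                     "top = %.3g, bottom = %.3g\n"),
              x$ic50, x$hill, x$top, x$bottom))
  invisible(x)
}

#' @export
predict.lc3_ic50_fit <- function(object, doses = NULL, ...) {
  if (is.null(doses)) doses <- object$data$dose
  object$bottom + (object$top - object$bottom) /
    (1 + (doses / object$ic50)^object$hill)
}

#' @rdname fit_ic50
#' @param x An `lc3_ic50_fit`.
#' @param ... Unused.
#' @export
tidy.lc3_ic50_fit <- function(x, ...) {
  est <- c(x$bottom, x$top, x$ic50, x$hill)
  se <- tryCatch({
    s <- summary(x$fit)$coefficients
    # delta method for the back-transformed ic50 standard error
    c(s["bottom", 2], s["top", 2], s["log_ic50", 2] * x$ic50, s["hill", 2])
  }, error = function(e) rep(NA_real_, 4))
  tibble(term = c("bottom", "top", "ic50", "hill"),
         estimate = est, std.error = se)
}

#' @rdname fit_ic50
#' @export
glance.lc3_ic50_fit <- function(x, ...) {
  r <- x$fit$fvec
  n <- length(r)
  p <- length(x$fit$par)
  tibble(sigma = if (n > p) sqrt(sum(r^2) / (n - p)) else NA_real_,
         rss = sum(r^2),
         nobs = n,
         niter = x$fit$niter,
         converged = x$fit$info %in% 1:4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fit_ic50
#' @param object An `lc3_ic50_fit`.
#' @export
autoplot.lc3_ic50_fit <- function(object, ...) {
  grid <- tibble(
    dose = exp(seq(log(min(object$data$dose)), log(max(object$data$dose)),
                   length.out = 200))
  )
  grid$response <- predict(object, grid$dose)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose,
                                            y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM)", y = "normalized response",
                  title = sprintf("IC50 = %.4g uM", object$ic50)) +
    ggplot2::theme_minimal()
}
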