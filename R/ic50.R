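#' Four-parameter logistic dose-response fit (IC50)
#'
#' Fits response = bottom + (top - bottom) / (1 + 10^(hill * (log10(conc)
#' - log10(IC50)))) on the log10 concentration axis, the standard model
#' for remaining-enzyme-activity and cell-viability curves. Responses are
#' percentages; concentrations are linear units (uM) and the returned
#' IC50 is in the same units. Zero concentrations (untreated controls)
#' cannot sit on the log axis and are dropped from the fit with a
#' warning; they should define the 100% normalization upstream.
#'
#' @param data data frame with columns `conc` (uM, >= 0) and `response`
#'   (percent).
#' @param constrain optional numeric `c(top, bottom)` to fix the
#'   asymptotes (e.g. `c(100, 0)`); default both free.
#' @param hill_start starting Hill slope (sign chosen from the data
#'   trend).
#' @return object of class `"ic50_fit"` with `IC50`, `hill`, `top`,
#'   `bottom`, `fit`, `data`.
#' @examples
#' d <- data.frame(conc = 10^seq(-1, 2, length.out = 9))
#' d$response <- 100 / (1 + d$conc / 5.45)
#' ic50_fit(d)
#' @export
ic50_fit <- function(data, constrain = NULL, hill_start = 1) {
  if (!is.data.frame(data) || !all(c("conc", "response") %in% names(data)))
    stop("dose-response data must have columns conc, response",
         call. = FALSE)
  if (any(!is.finite(data$conc)) || any(data$conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (any(data$conc == 0)) {
    warning("dropping conc = 0 rows (controls) from the log-scale fit")
    data <- data[data$conc > 0, , drop = FALSE]
  }
  if (length(unique(data$conc)) < 5L)
    stop("need >= 5 positive concentrations spanning the transition",
         call. = FALSE)
  if (var(data$response) == 0)
    stop("all responses identical: no transition to fit", call. = FALSE)

  rng <- range(data$response)
  ord <- order(data$conc)
  trend <- data$response[ord][length(ord)] - data$response[ord][1L]
  if (trend > 0)
    warning("response increases with concentration beyond noise; check sign")
  lx <- log10(data$conc)
  # midpoint starting value: concentration nearest the half response
  half <- mean(rng)
  start_l <- lx[which.min(abs(data$response - half))]
  y <- data$response
  fourpl <- function(p) p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + 10^(p[["hill"]] * (lx - p[["lic50"]])))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                     ptol = 1e-14)
  # raw Levenberg-Marquardt: near the optimum of noiseless curves that
  # never reach one asymptote the 4PL Jacobian is close to singular,
  # which the nls-object interface refuses but plain LM handles
  if (is.null(constrain)) {
    start <- c(top = rng[2L], bottom = rng[1L], hill = hill_start,
               lic50 = start_l)
    fit <- minpack.lm::nls.lm(start, fn = function(p) y - fourpl(p),
                              control = ctrl)
    cf <- as.list(fit$par)
  } else {
    if (length(constrain) != 2L || constrain[1L] <= constrain[2L])
      stop("constrain must be c(top, bottom) with top > bottom",
           call. = FALSE)
    start <- c(hill = hill_start, lic50 = start_l)
    fit <- minpack.lm::nls.lm(
      start,
      fn = function(p) y - fourpl(c(p, top = constrain[1L],
                                    bottom = constrain[2L])),
      control = ctrl)
    cf <- as.list(fit$par)
    cf$top <- constrain[1L]; cf$bottom <- constrain[2L]
  }
  if (fit$info %in% c(0, 5, 9))
    stop("dose-response fit did not converge: ", fit$message,
         call. = FALSE)
  if (cf$top <= cf$bottom)
    stop("fit collapsed: top <= bottom", call. = FALSE)
  structure(list(IC50 = 10^cf$lic50, hill = cf$hill, top = cf$top,
                 bottom = cf$bottom, constrained = !is.null(constrain),
                 fit = fit, data = data),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, digits = 3, ...) {
  cat(sprintf("4PL dose-response fit: IC50 = %.*g uM (hill = %.*g, top = %.*g, bottom = %.*g%s)\n",
              digits, x$IC50, digits, x$hill, digits, x$top, digits,
              x$bottom, if (x$constrained) ", constrained" else ""))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(IC50 = object$IC50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(object$hill * (log10(conc) - log10(object$IC50))))
}

#' @export
residuals.ic50_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.ic50_fit <- function(x, ...) {
  d <- x$data
  plot(d$conc, d$response, log = "x", xlab = "concentration (uM)",
       ylab = "response (%)", ...)
  cg <- 10^seq(log10(min(d$conc)), log10(max(d$conc)), length.out = 200)
  lines(cg, predict(x, data.frame(conc = cg)))
  abline(v = x$IC50, lty = 2)
  invisible(x)
}

#' Percent cell viability from optical densities
#'
#' 100 x mean OD of treated wells over mean OD of untreated wells, the
#' normalization used for MTT viability dose-response curves.
#'
#' @param od_treated optical densities of treated wells.
#' @param od_control optical densities of untreated control wells.
#' @return percent viability (scalar).
#' @export
percent_viability <- function(od_treated, od_control) {
  if (any(!is.finite(od_treated)) || any(!is.finite(od_control)))
    stop("optical densities must be finite", call. = FALSE)
  if (mean(od_control) <= 0)
    stop("control OD mean must be positive", call. = FALSE)
  100 * mean(od_treated) / mean(od_control)
}
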