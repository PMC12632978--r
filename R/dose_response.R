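#' Fit a four-parameter Hill (log-logistic) dose-response model
#'
#' Least-squares fit of
#' \deqn{r(d) = e_0 + (e_{max} - e_0) \frac{d^h}{d^h + EC_{50}^h}}
#' with the Hill coefficient bounded to `[0.5, 4]` and the EC50 bounded to
#' the positive dose range scaled by `[1e-2, 1e2]`. The optimizer
#' (Levenberg-Marquardt via \pkg{minpack.lm}, with a bounded Nelder/BFGS
#' fallback) is started from five fixed initial EC50 values spread
#' geometrically across the dose range; the best converged residual wins.
#'
#' @param series a dose series: `data.frame` with `dose_nM` and `response`
#'   (invariants: at least 4 strictly increasing doses).
#' @return an object of class `hill_fit` with components `coefficients`
#'   (`e0, emax, ec50_nM, hill`), `fitted.values`, `residuals`, `rss`,
#'   `converged`, and the data.
#' @examples
#' d <- c(0, 1, 3, 10, 30, 100, 300, 1000)
#' r <- 1 + 4 * d / (d + 10)
#' coef(fit_hill(data.frame(dose_nM = d, response = r)))
#' @export
fit_hill <- function(series) {
  check_series(series)
  d <- series$dose_nM
  r <- series$response
  pos <- d[d > 0]
  lo_ec <- min(pos) * 1e-2
  hi_ec <- max(pos) * 1e2
  starts_ec <- exp(seq(log(min(pos)), log(max(pos)), length.out = 5))
  lower <- c(e0 = -Inf, emax = -Inf, ec50 = lo_ec, hill = 0.5)
  upper <- c(e0 = Inf, emax = Inf, ec50 = hi_ec, hill = 4)

  hill_pred <- function(p, d) {
    p[1] + (p[2] - p[1]) * ifelse(d == 0, 0, d^p[4] / (d^p[4] + p[3]^p[4]))
  }
  rss_of <- function(p) sum((r - hill_pred(p, d))^2)

  best <- NULL
  for (ec in starts_ec) {
    start <- c(e0 = min(r), emax = max(r), ec50 = ec, hill = 1)
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(
        response ~ e0 + (emax - e0) * ifelse(dose_nM == 0, 0,
          dose_nM^hill / (dose_nM^hill + ec50^hill)),
        data = series, start = as.list(start),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))
      p <- stats::coef(m)[c("e0", "emax", "ec50", "hill")]
      list(par = p, rss = rss_of(p), ok = TRUE)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      o <- tryCatch(stats::optim(start, rss_of, method = "L-BFGS-B",
                                 lower = lower, upper = upper),
                    error = function(e) NULL)
      if (!is.null(o)) fit <- list(par = o$par, rss = o$value, ok = TRUE)
    }
    if (!is.null(fit) && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best))
    return(structure(list(coefficients = c(e0 = NA, emax = NA,
                                           ec50_nM = NA, hill = NA),
                          rss = NA_real_, converged = FALSE,
                          data = series),
                     class = "hill_fit"))
  p <- best$par
  fitted <- hill_pred(p, d)
  structure(list(coefficients = c(e0 = unname(p[1]), emax = unname(p[2]),
                                  ec50_nM = unname(p[3]), hill = unname(p[4])),
                 fitted.values = fitted, residuals = r - fitted,
                 rss = best$rss, converged = TRUE, data = series),
            class = "hill_fit")
}

check_series <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("dose_nM", "response") %in% names(series)))
  if (nrow(series) < 4) stopf("a dose series needs at least 4 doses")
  if (any(series$dose_nM < 0)) stopf("doses must be >= 0")
  if (is.unsorted(series$dose_nM, strictly = TRUE))
    stopf("doses must be strictly increasing")
  invisible(series)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
fitted.hill_fit <- function(object, ...) object$fitted.values

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  p <- object$coefficients
  d <- if (is.null(newdata)) object$data$dose_nM else {
    if (is.data.frame(newdata)) newdata$dose_nM else newdata
  }
  p["e0"] + (p["emax"] - p["e0"]) *
    ifelse(d == 0, 0, d^p["hill"] / (d^p["hill"] + p["ec50_nM"]^p["hill"]))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Four-parameter Hill fit\n")
  if (!x$converged) {
    cat("  fit failed to converge from all starts\n")
    return(invisible(x))
  }
  p <- x$coefficients
  cat(sprintf("  e0 = %.4g, emax = %.4g, ec50 = %.4g nM, hill = %.3g\n",
              p["e0"], p["emax"], p["ec50_nM"], p["hill"]))
  cat(sprintf("  RSS = %.4g over %d doses\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data$dose_nM
  plot(pmax(d, min(d[d > 0]) / 10), x$data$response, log = "x",
       xlab = "dose (nM)", ylab = "response", ...)
  dd <- exp(seq(log(min(d[d > 0]) / 10), log(max(d)), length.out = 100))
  graphics::lines(dd, predict(x, dd))
  invisible(x)
}

aic_rss <- function(rss, n, k) n * log(rss / n) + 2 * k

# best residual sum of squares of the unbounded monotone alternative
# r = a + b * log1p(d / K): logarithmic growth with a fitted dose scale K,
# the model-comparison stand-in for a non-saturating (clustering-like)
# response. For fixed K this is linear least squares; K is profiled over a
# geometric grid spanning the dose range.
fit_loggrowth_rss <- function(series) {
  d <- series$dose_nM
  r <- series$response
  pos <- d[d > 0]
  ks <- exp(seq(log(min(pos) / 10), log(max(pos)), length.out = 25))
  min(vapply(ks, function(k) {
    x <- log1p(d / k)
    sum(stats::residuals(stats::lm(r ~ x))^2)
  }, numeric(1)))
}

#' Classify a dose series as saturable, non-saturating, or no-signal
#'
#' Reproduces the dose-response triage: a series with too little amplitude is
#' `no_signal`; otherwise the bounded Hill fit competes against a monotone
#' unbounded alternative (linear in log dose) by AIC, and the Hill's own
#' plateau is checked -- the fitted-curve slope between the two highest
#' doses, relative to the fitted amplitude, must stay below `epsilon` per
#' log-unit. Saturable means the Hill wins and plateaus; anything else that
#' clears the noise floor is non-saturating. Using the fitted (monotone)
#' curve for the plateau test makes the rule robust both to well noise and to
#' a high-dose hook: doses beyond the response peak cannot drag the slope up.
#' The whole rule is invariant to affine rescaling of the responses.
#'
#' @param series a dose series (`dose_nM`, `response`).
#' @param noise_floor minimal amplitude (same units as `response`) for a
#'   series to count as signaling; estimate it from assay controls, e.g.
#'   `3 * sd(control_mfi)`.
#' @param epsilon plateau threshold: maximal fitted slope between the top two
#'   doses as a fraction of amplitude per natural-log dose unit
#'   (default 0.1).
#' @return an object of class `mechanism_call`: list with `label` (one of
#'   `saturable`, `non_saturating`, `no_signal`), `fit` (the `hill_fit`),
#'   and `evidence` (AIC of the log-linear alternative minus AIC of the
#'   Hill; positive favours the Hill).
#' @export
classify_dose_response <- function(series, noise_floor, epsilon = 0.1) {
  check_series(series)
  if (noise_floor < 0) stopf("noise_floor must be >= 0")
  fit <- fit_hill(series)
  n <- nrow(series)
  d <- series$dose_nM
  r <- series$response

  # amplitude read from the ends of the dose range, averaging two points at
  # each end so single noisy wells cannot decide the no-signal gate
  low <- mean(r[seq_len(min(2, n))])
  top <- mean(r[order(d, decreasing = TRUE)[seq_len(min(2, n))]])
  amplitude_obs <- max(r) - min(r[seq_len(min(2, n))])
  if (!fit$converged || (top - low) < noise_floor) {
    label <- "no_signal"
    return(structure(list(label = label, fit = fit, evidence = NA_real_),
                     class = "mechanism_call"))
  }

  aic_hill <- aic_rss(fit$rss, n, 4)
  aic_lin <- aic_rss(fit_loggrowth_rss(series), n, 3)
  evidence <- aic_lin - aic_hill

  p <- fit$coefficients
  amp_fit <- abs(p["emax"] - p["e0"])
  top_doses <- sort(d, decreasing = TRUE)[1:2]
  f2 <- predict(fit, top_doses)
  slope <- (f2[1] - f2[2]) / (log(top_doses[1]) - log(top_doses[2]))
  rel_slope <- if (amp_fit > 0) slope / amp_fit else 0

  label <- if (evidence > 0 && rel_slope < epsilon) "saturable"
           else "non_saturating"
  structure(list(label = label, fit = fit, evidence = unname(evidence),
                 rel_slope = unname(rel_slope)),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("mechanism call: %s", x$label))
  if (!is.na(x$evidence))
    cat(sprintf(" (AIC evidence %.2f, plateau slope %.3f)",
                x$evidence, x$rel_slope))
  cat("\n")
  invisible(x)
}

#' Classify many dose series from a long table
#'
#' @param series_table `data.frame` with `construct_id, dose_nM, response`
#'   (and optionally `pathway, cell_type`).
#' @param noise_floor,epsilon see [classify_dose_response()].
#' @return `data.frame` with one row per construct: `construct_id, label,
#'   e0, emax, ec50_nM, hill, evidence`.
#' @export
classify_series_table <- function(series_table, noise_floor, epsilon = 0.1) {
  ids <- unique(series_table$construct_id)
  rows <- lapply(ids, function(id) {
    s <- series_table[series_table$construct_id == id, ]
    s <- s[order(s$dose_nM), ]
    mc <- classify_dose_response(s[, c("dose_nM", "response")],
                                 noise_floor = noise_floor, epsilon = epsilon)
    p <- mc$fit$coefficients
    data.frame(construct_id = id, label = mc$label,
               e0 = p["e0"], emax = p["emax"], ec50_nM = p["ec50_nM"],
               hill = p["hill"], evidence = mc$evidence,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
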