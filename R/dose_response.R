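#' Growth-kinetics linearity check for the bioluminescence assay
#'
#' The spheroid cytotoxicity assay assumes luminescence signal is directly
#' proportional to viable cell mass. This QC fits a least-squares line
#' signal ~ seeded cells on day-0 readouts over a dilution series of seeded
#' cell amounts and reports slope, intercept and R-squared, with a
#' configurable gate on R-squared.
#'
#' @param cells numeric vector of seeded cell amounts.
#' @param signal luminescence counts at day 0, same length.
#' @param r2_threshold QC gate on R-squared (default 0.9).
#' @return list of class `growth_qc`: `slope`, `intercept`, `r_squared`,
#'   `slope_se`, `pass`, and the underlying `lm` fit.
#' @export
growth_linearity <- function(cells, signal, r2_threshold = 0.9) {
  if (length(unique(cells)) < 3)
    stop("need at least 3 distinct seeded-cell amounts")
  fit <- stats::lm(signal ~ cells)
  sm <- suppressWarnings(summary(fit))  # exact linearity warns harmlessly
  r2 <- if (stats::var(signal) == 0) 0 else sm$r.squared
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              slope_se = sm$coefficients["cells", "Std. Error"],
              r_squared = r2, pass = r2 >= r2_threshold, fit = fit)
  class(out) <- "growth_qc"
  out
}

#' @export
print.growth_qc <- function(x, ...) {
  cat(sprintf("signal ~ cells: slope %.4g (SE %.3g), R^2 = %.4f [%s]\n",
              x$slope, x$slope_se, x$r_squared,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

# 4PL response: decreasing from `top` (low dose) to `bottom` (high dose)
# with hill > 0; `log_ic50` is log10(IC50 in uM).
pl4_response <- function(d, top, bottom, hill, log_ic50) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(d) - log_ic50)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits the 4PL model
#' \deqn{R(d) = bottom + \frac{top - bottom}{1 + 10^{hill (\log_{10} d - \log_{10} IC_{50})}}}
#' to normalized responses by least squares, using Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) from multiple starting values on a log10-IC50 grid
#' spanning the dose range; the best-SSE converged fit wins. IC50 is the
#' relative (curve midpoint) convention: R(IC50) = (top + bottom)/2 by
#' construction.
#'
#' Responses are expected normalized to the untreated (dose 0) mean of 1;
#' dose-0 wells anchor the normalization but cannot enter the logistic (log
#' dose is undefined) and are dropped from the fit. When a `replicate`
#' vector is supplied, the curve is additionally refit per replicate and the
#' per-replicate IC50s provide `ic50_sd`, the replicate-level dispersion that
#' the downstream Welch comparison uses.
#'
#' @param dose doses in uM; 0 allowed (dropped from the fit).
#' @param response normalized signals, same length.
#' @param replicate optional replicate index per observation.
#' @param constrain with fewer than 4 distinct positive doses, fix
#'   `top = 1`, `bottom = 0` and fit only hill and IC50 (default auto).
#' @param n_starts number of log10-IC50 grid starts (default 7).
#' @return object of class `pl4_fit` with elements `coefficients`
#'   (top, bottom, hill, ic50), `ic50_sd`, `replicate_ic50`, `sse`,
#'   `residuals`, `fitted`, `data`, `convergence`.
#' @export
fit_4pl <- function(dose, response, replicate = NULL, constrain = NULL,
                    n_starts = 7) {
  keep <- dose > 0
  d <- dose[keep]; y <- response[keep]
  rep_id <- if (is.null(replicate)) NULL else replicate[keep]
  nd <- length(unique(d))
  if (nd < 2) stop("need at least 2 distinct positive doses")
  if (is.null(constrain)) constrain <- nd < 4
  if (isTRUE(suppressWarnings(stats::cor(log10(d), y)) > 0.5))
    warning("no inhibition: response increases with dose")

  lr <- range(log10(d))
  starts <- seq(lr[1], lr[2], length.out = n_starts)
  df <- data.frame(d = d, y = y)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch({
      if (constrain) {
        minpack.lm::nlsLM(
          y ~ pl4_response(d, 1, 0, hill, log_ic50), data = df,
          start = list(hill = 1, log_ic50 = s),
          lower = c(0.05, lr[1] - 3), upper = c(10, lr[2] + 3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          y ~ pl4_response(d, top, bottom, hill, log_ic50), data = df,
          start = list(top = max(y), bottom = min(y), hill = 1, log_ic50 = s),
          lower = c(-Inf, -Inf, 0.05, lr[1] - 3),
          upper = c(Inf, Inf, 10, lr[2] + 3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best))
    stop("4PL fit failed to converge from any of ", n_starts,
         " starting values (", nd, " distinct doses)")
  cf <- stats::coef(best$fit)
  if (constrain) cf <- c(top = 1, bottom = 0, cf)
  if (cf["top"] < cf["bottom"]) {  # canonical orientation
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
    cf["hill"] <- -cf["hill"]
  }
  coefs <- c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
             hill = unname(cf["hill"]), ic50 = unname(10^cf["log_ic50"]))

  rep_ic50 <- NULL; ic50_sd <- NA_real_
  if (!is.null(rep_id) && length(unique(rep_id)) >= 2) {
    rep_ic50 <- vapply(split(seq_along(d), rep_id), function(idx) {
      f <- tryCatch(fit_4pl(d[idx], y[idx], replicate = NULL,
                            constrain = constrain, n_starts = n_starts),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$coefficients[["ic50"]]
    }, numeric(1))
    ic50_sd <- stats::sd(rep_ic50, na.rm = TRUE)
  }

  out <- list(coefficients = coefs, ic50_sd = ic50_sd,
              replicate_ic50 = rep_ic50, sse = best$sse,
              fitted = stats::fitted(best$fit),
              residuals = stats::resid(best$fit),
              data = df, convergence = best$fit$convInfo)
  class(out) <- "pl4_fit"
  out
}

#' @export
print.pl4_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("4PL dose-response fit\n")
  cat(sprintf("  IC50 = %.4g uM%s\n", cf["ic50"],
              if (is.na(x$ic50_sd)) "" else
                sprintf(" (SD %.3g, %d replicates)", x$ic50_sd,
                        length(x$replicate_ic50))))
  cat(sprintf("  top = %.3f, bottom = %.3f, hill = %.3f, SSE = %.4g\n",
              cf["top"], cf["bottom"], cf["hill"], x$sse))
  invisible(x)
}

#' @export
coef.pl4_fit <- function(object, ...) object$coefficients

#' @export
residuals.pl4_fit <- function(object, ...) object$residuals

#' @export
fitted.pl4_fit <- function(object, ...) object$fitted

#' @export
predict.pl4_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$d else
    if (is.data.frame(newdata)) newdata$d else newdata
  cf <- object$coefficients
  pl4_response(d, cf["top"], cf["bottom"], cf["hill"], log10(cf["ic50"]))
}

#' @export
summary.pl4_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$replicate_ic50)) {
    cat("per-replicate IC50s (uM):\n")
    print(signif(object$replicate_ic50, 4))
  }
  invisible(object)
}

#' @export
plot.pl4_fit <- function(x, ...) {
  d <- x$data$d
  grid <- 10^seq(log10(min(d)) - 0.5, log10(max(d)) + 0.5, length.out = 100)
  plot(x$data$d, x$data$y, log = "x", xlab = "dose (uM)",
       ylab = "relative signal", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$coefficients["ic50"], lty = 2)
  invisible(x)
}

#' Welch comparison of IC50 values between assay formats
#'
#' Compares the per-replicate IC50s of two fits (typically 2D monolayer vs
#' 3D spheroid) with Welch's unequal-variance t-test on log10(IC50) -
#' IC50s are positive and roughly log-normal, so the test is run on the log
#' scale - using the Welch-Satterthwaite degrees of freedom and a two-sided
#' p-value.
#'
#' @param fit_a,fit_b `pl4_fit` objects carrying >= 2 per-replicate IC50s
#'   each (alternatively, raw numeric vectors of replicate IC50s).
#' @param alpha significance level for the verdict (default 0.05).
#' @return list of class `ic50_comparison`: `ic50_a`, `ic50_b`, `t`, `df`,
#'   `p_value`, `significant`, `alpha`.
#' @export
compare_ic50 <- function(fit_a, fit_b, alpha = 0.05) {
  get_reps <- function(f, nm) {
    r <- if (inherits(f, "pl4_fit")) f$replicate_ic50 else f
    r <- r[is.finite(r)]
    if (length(r) < 2)
      stop("fewer than 2 replicate IC50s on side ", nm)
    r
  }
  a <- get_reps(fit_a, "A"); b <- get_reps(fit_b, "B")
  tt <- stats::t.test(log10(a), log10(b), var.equal = FALSE)
  out <- list(ic50_a = mean(a), ic50_b = mean(b),
              t = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value, significant = tt$p.value < alpha,
              alpha = alpha)
  class(out) <- "ic50_comparison"
  out
}

#' @export
print.ic50_comparison <- function(x, ...) {
  cat(sprintf("Welch test on log10 IC50: t = %.3f, df = %.2f, p = %.4g %s\n",
              x$t, x$df, x$p_value,
              if (x$significant) sprintf("(significant at %.2g)", x$alpha)
              else "(n.s.)"))
  cat(sprintf("  mean IC50 A = %.4g uM, B = %.4g uM\n", x$ic50_a, x$ic50_b))
  invisible(x)
}

#' Normalize plate signals to the untreated control
#'
#' Divides every well's signal by the mean dose-0 signal of the same model,
#' condition and day.
#'
#' @param plate long-format data.frame with columns `model_id`, `condition`,
#'   `dose_uM`, `replicate`, `day`, `signal`.
#' @return the data.frame with an added `response` column.
#' @export
normalize_plate <- function(plate) {
  key <- interaction(plate$model_id, plate$condition, plate$day, drop = TRUE)
  ctrl <- tapply(plate$signal[plate$dose_uM == 0],
                 key[plate$dose_uM == 0], mean)
  if (anyNA(ctrl[key])) stop("missing dose-0 control wells for some group")
  plate$response <- plate$signal / as.numeric(ctrl[as.character(key)])
  plate
}

#' Fit dose-response curves for every model and condition on a plate
#'
#' Normalizes the plate ([normalize_plate()]), restricts to the endpoint
#' `day`, fits a 4PL curve per (model, condition) with per-replicate IC50s,
#' and - where both conditions are present - compares 2D against spheroid
#' IC50s with [compare_ic50()].
#'
#' @param plate long-format readout (see [normalize_plate()]).
#' @param day endpoint day used for the dose-response (default the maximum
#'   day present).
#' @param alpha significance level for the Welch verdicts.
#' @return list of class `dose_response_table`: `fits` (named list of
#'   `pl4_fit`), `table` (per-model IC50 summary with Welch p), `alpha`.
#' @export
fit_plate <- function(plate, day = max(plate$day), alpha = 0.05) {
  plate <- normalize_plate(plate)
  ep <- plate[plate$day == day, , drop = FALSE]
  combos <- unique(ep[, c("model_id", "condition")])
  fits <- list()
  for (i in seq_len(nrow(combos))) {
    sel <- ep$model_id == combos$model_id[i] &
      ep$condition == combos$condition[i]
    nm <- paste(combos$model_id[i], combos$condition[i], sep = ".")
    fits[[nm]] <- fit_4pl(ep$dose_uM[sel], ep$response[sel],
                          replicate = ep$replicate[sel])
  }
  rows <- lapply(unique(combos$model_id), function(mid) {
    f2 <- fits[[paste(mid, "2D", sep = ".")]]
    f3 <- fits[[paste(mid, "spheroid", sep = ".")]]
    cmp <- if (!is.null(f2) && !is.null(f3)) compare_ic50(f2, f3, alpha)
    data.frame(
      model_id = mid,
      ic50_2D = if (is.null(f2)) NA_real_ else f2$coefficients[["ic50"]],
      sd_2D = if (is.null(f2)) NA_real_ else f2$ic50_sd,
      ic50_3D = if (is.null(f3)) NA_real_ else f3$coefficients[["ic50"]],
      sd_3D = if (is.null(f3)) NA_real_ else f3$ic50_sd,
      p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
      shifted = if (is.null(cmp)) NA else cmp$significant,
      stringsAsFactors = FALSE)
  })
  out <- list(fits = fits, table = do.call(rbind, rows), alpha = alpha)
  class(out) <- "dose_response_table"
  out
}

#' @export
print.dose_response_table <- function(x, ...) {
  cat("dose-response summary (IC50 in uM):\n")
  print.data.frame(x$table, digits = 4)
  invisible(x)
}
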