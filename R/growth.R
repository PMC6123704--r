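# Growth-rate estimation from confluence time series and GI50 estimation from
# dose-inhibition curves.

#' Exponential growth rate from a confluence time series
#'
#' Fits an exponential curve by least-squares regression of log confluence on
#' time; replicate wells are pooled into a single regression. Points with
#' non-positive confluence are dropped, and by default only points at or below
#' 80\% confluence are used (the validity range of the steady-state model).
#'
#' @param time_h Numeric vector of sampling times (hours).
#' @param confluence Numeric vector of confluence fractions, aligned with
#'   \code{time_h}.
#' @param max_confluence Upper confluence bound of the fitting window
#'   (default 0.80; set to \code{Inf} to disable).
#' @return List with \code{rate} (per hour), \code{se}, \code{intercept}
#'   (log confluence at t = 0), \code{n}.
#' @export
fit_growth_rate <- function(time_h, confluence, max_confluence = 0.80) {
  stopifnot(length(time_h) == length(confluence))
  ok <- !is.na(time_h) & !is.na(confluence) & confluence > 0 &
    confluence <= max_confluence
  if (sum(ok) < 3L) stop("need at least 3 positive confluence points to fit")
  X <- cbind(intercept = 1, time = time_h[ok])
  f <- ols_fit(X, log(confluence[ok]))
  list(rate = unname(f$coef[2]), se = unname(f$se[2]),
       intercept = unname(f$coef[1]), n = sum(ok))
}

#' Growth inhibition relative to the untreated condition
#'
#' \code{inhibition(d) = 1 - rate(d) / rate_untreated}. Values above 1 (net
#' death) or below 0 (growth stimulation) are possible and retained.
#'
#' @param rates Numeric vector of growth rates per dose (per hour).
#' @param rate_untreated Untreated growth rate (must be positive).
#' @return Numeric vector of inhibition fractions.
#' @export
inhibition_curve <- function(rates, rate_untreated) {
  if (is.na(rate_untreated) || length(rate_untreated) != 1L) {
    stop("untreated growth rate missing")
  }
  stopifnot(rate_untreated > 0)
  1 - rates / rate_untreated
}

#' Estimate the GI50 from a dose-inhibition curve
#'
#' Fits the two-parameter Hill curve
#' \code{inhibition(d) = 1 / (1 + (gi50 / d)^h)} to the observed growth
#' inhibitions by nonlinear least squares on the log10-dose scale. The GI50 is
#' the dose at 50\% growth-rate reduction. Dose 0 defines the untreated rate
#' only and is excluded from the sigmoid fit. A four-parameter logistic with
#' free asymptotes is available via \code{four_param = TRUE}.
#'
#' @param doses Numeric vector of doses (mM); zeros are dropped.
#' @param inhibitions Inhibition fractions aligned with \code{doses}.
#' @param four_param If TRUE fit a 4-parameter logistic (free lower/upper
#'   asymptotes); GI50 remains the dose at inhibition 0.5 of the fitted curve.
#' @return List with \code{gi50}, \code{hill_slope}, \code{fit_rsq},
#'   \code{extrapolated} (TRUE when 0.5 lies outside the observed inhibition
#'   range), \code{confident} (TRUE when the observed inhibitions span at
#'   least [0.2, 0.8]), \code{no_inhibition} flag and the fitted values.
#' @export
estimate_gi50 <- function(doses, inhibitions, four_param = FALSE) {
  stopifnot(length(doses) == length(inhibitions))
  ok <- !is.na(doses) & !is.na(inhibitions) & doses > 0
  d <- doses[ok]; y <- inhibitions[ok]
  if (length(unique(d)) < 4L) stop("need at least 4 distinct non-zero doses")
  ld <- log10(d)
  no_inhibition <- max(y) < 0.2
  extrapolated <- min(y) > 0.5 || max(y) < 0.5
  confident <- min(y) <= 0.2 && max(y) >= 0.8

  # starting values: GI50 from linear interpolation at inhibition 0.5
  ys <- y[order(ld)]; ls <- sort(ld)
  cross <- which(diff(sign(ys - 0.5)) != 0)
  l0 <- if (length(cross) > 0) {
    i <- cross[1]
    ls[i] + (0.5 - ys[i]) * (ls[i + 1] - ls[i]) / (ys[i + 1] - ys[i])
  } else ls[which.min(abs(ys - 0.5))]
  start <- list(lg = l0, h = 1)

  sse <- function(par) {
    pred <- 1 / (1 + 10^(par[2] * (par[1] - ld)))
    sum((y - pred)^2)
  }
  # scaleOffset makes the nls convergence test valid for zero-residual fits
  fit <- tryCatch(
    stats::nls(y ~ 1 / (1 + 10^(h * (lg - ld))), start = start,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    pred <- as.numeric(stats::fitted(fit))
  } else {
    opt <- stats::optim(unlist(start), sse, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (opt$convergence != 0) {
      if (no_inhibition) {
        # essentially flat inhibition: the sigmoid location is unidentifiable
        return(list(gi50 = NA_real_, hill_slope = NA_real_, fit_rsq = NA_real_,
                    extrapolated = TRUE, confident = FALSE,
                    no_inhibition = TRUE, lower_asymptote = 0,
                    upper_asymptote = 1, doses = d, inhibitions = y,
                    fitted = rep(mean(y), length(y))))
      }
      stop(sprintf("GI50 fit did not converge (optim code %d, sse %.4g)",
                   opt$convergence, opt$value))
    }
    cf <- c(lg = unname(opt$par[1]), h = unname(opt$par[2]))
    pred <- 1 / (1 + 10^(cf[["h"]] * (cf[["lg"]] - ld)))
  }
  lower <- 0; upper <- 1
  if (four_param) {
    sse4 <- function(par) {
      pr <- par[3] + (par[4] - par[3]) / (1 + 10^(par[2] * (par[1] - ld)))
      sum((y - pr)^2)
    }
    opt4 <- stats::optim(c(cf[["lg"]], cf[["h"]], 0, 1), sse4,
                         method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-12))
    p4 <- opt4$par
    lower <- p4[3]; upper <- p4[4]
    pred <- p4[3] + (p4[4] - p4[3]) / (1 + 10^(p4[2] * (p4[1] - ld)))
    # dose where the fitted curve crosses inhibition 0.5
    frac <- (0.5 - p4[3]) / (p4[4] - p4[3])
    if (frac <= 0 || frac >= 1) {
      cf <- c(lg = NA_real_, h = p4[2])
    } else {
      cf <- c(lg = p4[1] - log10(frac / (1 - frac)) / p4[2], h = p4[2])
    }
  }
  ss_tot <- sum((y - mean(y))^2)
  rsq <- if (ss_tot > 0) 1 - sum((y - pred)^2) / ss_tot else NA_real_
  list(
    gi50 = unname(10^cf[["lg"]]),
    hill_slope = unname(cf[["h"]]),
    fit_rsq = rsq,
    extrapolated = extrapolated,
    confident = confident,
    no_inhibition = no_inhibition,
    lower_asymptote = lower,
    upper_asymptote = upper,
    doses = d, inhibitions = y, fitted = unname(pred)
  )
}

#' Dose-response analysis of a confluence table
#'
#' Convenience wrapper: fits growth rates per dose from a long confluence
#' table, converts them to inhibitions relative to dose 0 and estimates the
#' GI50.
#'
#' @param confluence_df data.frame with columns \code{time_h}, \code{dose},
#'   \code{confluence} (replicates pooled).
#' @param ... Passed to \code{\link{estimate_gi50}}.
#' @return List with \code{dose_table} (dose, rate, se, inhibition) and the
#'   GI50 fit.
#' @export
dose_response <- function(confluence_df, ...) {
  stopifnot(all(c("time_h", "dose", "confluence") %in% names(confluence_df)))
  doses <- sort(unique(confluence_df$dose))
  if (!0 %in% doses) stop("missing untreated condition (dose 0)")
  rates <- lapply(doses, function(dd) {
    sub <- confluence_df[confluence_df$dose == dd, ]
    fit_growth_rate(sub$time_h, sub$confluence)
  })
  rate <- vapply(rates, `[[`, numeric(1), "rate")
  se <- vapply(rates, `[[`, numeric(1), "se")
  inh <- inhibition_curve(rate, rate[doses == 0])
  gi50 <- estimate_gi50(doses, inh, ...)
  list(dose_table = data.frame(dose = doses, rate = rate, se = se,
                               inhibition = inh),
       gi50 = gi50)
}
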