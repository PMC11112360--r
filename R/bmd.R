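# --- benchmark dose from a fitted curve, with profile-likelihood limits ----

# Smallest positive dose at which |mu(d) - mu(0)| reaches bmr, found by a
# log-spaced grid scan (first sign change) refined with uniroot. Returns Inf
# when the curve never departs from control by bmr at or below dmax.
solve_bmd <- function(mean_fn, params, bmr, dmax) {
  mu0 <- mean_fn(params, 0)
  h <- function(d) abs(mean_fn(params, d) - mu0) - bmr
  grid <- dmax * 10^seq(-9, 0, length.out = 720)
  hv <- vapply(grid, h, numeric(1))
  hit <- which(hv >= 0)
  if (length(hit) == 0) return(Inf)
  i <- hit[1]
  if (i == 1) return(grid[1])
  stats::uniroot(h, c(grid[i - 1], grid[i]), tol = dmax * 1e-12)$root
}

# Index of the parameter eliminated by the BMR constraint, per model. Every
# family has one amplitude-like parameter solvable in closed form from
# (bmd, sigma, other parameters), which makes joint profiling of the BMD
# a bounded optimization over the remaining mean parameters and sigma.
elim_index <- function(model) {
  switch(model, linear = 2L, poly2 = 2L, power = 2L, hill = 2L,
         exp2 = 1L, exp3 = 1L, exp4 = 1L, exp5 = 1L)
}

# Reconstruct the full mean-parameter vector from the free parameters, the
# profiled BMD `b`, sigma (the 1-SD BMR) and the response direction.
elim_solve <- function(model, free, b, sigma, dir) {
  switch(model,
    linear = c(free[1], dir * sigma / b),
    poly2 = c(free[1], (dir * sigma - free[2] * b^2) / b, free[2]),
    power = c(free[1], dir * sigma / b^free[2], free[2]),
    hill = {
      n <- free[2]; k <- free[3]
      c(free[1], dir * sigma * (k^n + b^n) / b^n, n, k)
    },
    exp2 = {
      den <- abs(expm1(dir * min(free[1] * b, 500)))
      c(sigma / max(den, 1e-12), free[1])
    },
    exp3 = {
      den <- abs(expm1(dir * min((free[1] * b)^free[2], 500)))
      c(sigma / max(den, 1e-12), free[1], free[2])
    },
    exp4 = {
      den <- abs(free[2] - 1) * (1 - exp(-free[1] * b))
      c(sigma / max(den, 1e-12), free[1], free[2])
    },
    exp5 = {
      den <- abs(free[2] - 1) * (1 - exp(-(free[1] * b)^free[3]))
      c(sigma / max(den, 1e-12), free[1], free[2], free[3])
    })
}

# Profile log-likelihood at a fixed BMD value: maximize the normal
# log-likelihood over the remaining mean parameters and sigma, with the
# amplitude parameter eliminated through the BMR constraint (joint profiling
# of sigma, since the 1-SD BMR ties the amplitude to the current sigma).
profile_loglik_at <- function(b, model, doses, values, dir, start_free,
                              start_sigma, bounds_free) {
  N <- length(values)
  mf <- model_mean_fn(model, dir)
  nll <- function(th) {
    sigma <- th[length(th)]
    free <- th[-length(th)]
    full <- elim_solve(model, free, b, sigma, dir)
    r <- values - mf(full, doses)
    val <- N / 2 * log(2 * pi * sigma^2) + sum(r^2) / (2 * sigma^2)
    if (!is.finite(val)) 1e30 else val
  }
  lower <- c(bounds_free$lower, 1e-8)
  upper <- c(bounds_free$upper, Inf)
  st <- pmin(pmax(c(start_free, start_sigma), lower), upper)
  fit <- tryCatch(
    stats::optim(st, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(loglik = -Inf, par = st))
  list(loglik = -fit$value, par = fit$par)
}

# One-sided profile bound: walk geometrically away from the MLE BMD until the
# profile deviance exceeds the chi-square cutoff, then bisect. Warm starts
# propagate along the walk. Returns the walk limit when the deviance never
# crosses (a very shallow profile).
profile_bound <- function(side, fit, bmd, doses, values, cutoff = 2.706,
                          max_steps = 60) {
  model <- fit$model
  dir <- fit$dir
  ei <- elim_index(model)
  bounds <- model_bounds(model, doses, values, dir)
  bounds_free <- list(lower = bounds$lower[-ei], upper = bounds$upper[-ei])
  free0 <- unname(fit$params[-ei])
  sig0 <- fit$sigma
  llhat <- fit$loglik
  dev_at <- local({
    warm_free <- free0; warm_sig <- sig0
    function(b) {
      pl <- profile_loglik_at(b, model, doses, values, dir, warm_free,
                              warm_sig, bounds_free)
      if (is.finite(pl$loglik)) {
        warm_free <<- pl$par[-length(pl$par)]
        warm_sig <<- pl$par[length(pl$par)]
      }
      2 * (llhat - pl$loglik)
    }
  })
  step <- if (side == "lower") 0.7 else 1.4
  b_prev <- bmd
  d_prev <- 0
  for (i in seq_len(max_steps)) {
    b <- bmd * step^i
    d <- dev_at(b)
    if (is.finite(d) && d >= cutoff) {
      root <- tryCatch(
        stats::uniroot(function(x) dev_at(x) - cutoff,
                       lower = min(b, b_prev), upper = max(b, b_prev),
                       tol = bmd * 1e-6)$root,
        error = function(e) b)
      return(root)
    }
    b_prev <- b
    d_prev <- d
  }
  bmd * step^max_steps
}

#' Benchmark dose and profile-likelihood confidence limits from one fit
#'
#' The BMD solves `|mu(d) - mu(0)| = control_sd` (a benchmark response of one
#' standard deviation). BMDL and BMDU are profile-likelihood limits at the
#' given confidence level: each one-sided bound uses the chi-square(1) cutoff
#' `qchisq(2 * confidence - 1, 1)` (2.706 at 0.95), with sigma profiled
#' jointly.
#'
#' @param fit a converged `dr_model_fit`.
#' @param doses,values the data the model was fit to.
#' @param control_sd benchmark response in log2 units; defaults to the fit's
#'   modeled sigma.
#' @param confidence confidence level for the limits (default 0.95).
#' @return named numeric `c(bmd, bmdl, bmdu)`; `bmd = Inf` when the curve
#'   never crosses the BMR at or below the highest dose.
#' @export
bmd_from_fit <- function(fit, doses, values, control_sd = fit$sigma,
                         confidence = 0.95) {
  stopifnot(inherits(fit, "dr_model_fit"), isTRUE(fit$converged))
  dmax <- max(doses)
  mf <- model_mean_fn(fit$model, fit$dir)
  bmd <- solve_bmd(mf, fit$params, control_sd, dmax)
  if (!is.finite(bmd))
    return(c(bmd = Inf, bmdl = NA_real_, bmdu = NA_real_))
  cutoff <- stats::qchisq(2 * confidence - 1, df = 1)
  bmdl <- profile_bound("lower", fit, bmd, doses, values, cutoff)
  bmdu <- profile_bound("upper", fit, bmd, doses, values, cutoff)
  c(bmd = bmd, bmdl = min(bmdl, bmd), bmdu = max(bmdu, bmd))
}

#' BMD sanity-filter parameters
#'
#' Records with a BMD above the highest tested dose or with a BMDU/BMDL
#' ratio above `max_bmdu_bmdl_ratio` (default 40) are removed from further
#' analysis.
#'
#' @param max_bmd highest tested dose (mg/kg/d).
#' @param max_bmdu_bmdl_ratio maximum allowed BMDU/BMDL ratio.
#' @return a list of class `bmd_filter_params`.
#' @export
bmd_filter_params <- function(max_bmd, max_bmdu_bmdl_ratio = 40) {
  stopifnot(max_bmd > 0, max_bmdu_bmdl_ratio > 1)
  structure(list(max_bmd = max_bmd,
                 max_bmdu_bmdl_ratio = max_bmdu_bmdl_ratio),
            class = "bmd_filter_params")
}

#' Fit all dose-response models to one probeset and derive its BMD
#'
#' The core estimator: fits the eight continuous dose-response families by
#' maximum likelihood, selects the best model under the AIC / nested
#' polynomial / flagged-Hill rules (see [select_best_model()]), and computes
#' the benchmark dose with profile-likelihood limits at a 1-SD benchmark
#' response.
#'
#' @param values numeric per-sample log2 responses.
#' @param doses numeric per-sample doses (control plus >= 2 positive levels).
#' @param models model families to fit (default all eight).
#' @param control_sd `"modeled"` (the selected fit's constant-variance sigma,
#'   the default) or `"empirical"` (the control group's sample SD) as the
#'   benchmark response.
#' @param confidence confidence level for BMDL/BMDU.
#' @return object of class `bmd_fit`: list with `fits` (all per-family
#'   fits), `best` (selected `dr_model_fit`, or NULL), `bmd`, `bmdl`, `bmdu`,
#'   `bmr`, `doses`, `values`.
#' @export
#' @examples
#' d <- rep(c(0, 10, 100, 1000), each = 3)
#' y <- 8 + 0.002 * d + rnorm(length(d), sd = 0.1)
#' f <- fit_bmd(y, d)
#' print(f)
fit_bmd <- function(values, doses, models = bmd_model_names(),
                    control_sd = c("modeled", "empirical"),
                    confidence = 0.95) {
  control_sd <- match.arg(control_sd)
  dir <- response_direction(doses, values)
  fits <- lapply(models, fit_dose_response, doses = doses, values = values,
                 dir = dir)
  names(fits) <- models
  best <- select_best_model(fits, min(doses[doses > 0]), length(values))
  if (is.null(best)) {
    out <- list(fits = fits, best = NULL, bmd = NA_real_, bmdl = NA_real_,
                bmdu = NA_real_, bmr = NA_real_, doses = doses,
                values = values)
    return(structure(out, class = "bmd_fit"))
  }
  bmr <- if (control_sd == "modeled") best$sigma
         else stats::sd(values[doses == 0])
  ci <- bmd_from_fit(best, doses, values, control_sd = bmr,
                     confidence = confidence)
  structure(list(fits = fits, best = best, bmd = unname(ci["bmd"]),
                 bmdl = unname(ci["bmdl"]), bmdu = unname(ci["bmdu"]),
                 bmr = bmr, doses = doses, values = values),
            class = "bmd_fit")
}

#' @export
print.bmd_fit <- function(x, ...) {
  cat("Benchmark-dose fit\n")
  if (is.null(x$best)) {
    cat("  no eligible model\n")
    return(invisible(x))
  }
  cat("  best model:", x$best$model,
      if (isTRUE(x$best$flagged)) "(flagged)" else "", "\n")
  cat(sprintf("  BMD = %.4g [BMDL %.4g, BMDU %.4g] mg/kg/d (BMR = %.3g log2)\n",
              x$bmd, x$bmdl, x$bmdu, x$bmr))
  invisible(x)
}

#' @export
summary.bmd_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(model = f$model, converged = f$converged,
               aic = f$aic, fit_pvalue = f$fit_pvalue, sigma = f$sigma,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  out <- list(models = tab[order(tab$aic), ],
              best = if (is.null(object$best)) NA_character_
                     else object$best$model,
              bmd = object$bmd, bmdl = object$bmdl, bmdu = object$bmdu,
              bmr = object$bmr)
  class(out) <- "summary.bmd_fit"
  out
}

#' @export
print.summary.bmd_fit <- function(x, ...) {
  cat("Model comparison (sorted by AIC):\n")
  print(x$models, row.names = FALSE, digits = 4)
  cat(sprintf("best: %s; BMD = %.4g [%.4g, %.4g]\n",
              x$best, x$bmd, x$bmdl, x$bmdu))
  invisible(x)
}

#' @export
coef.bmd_fit <- function(object, ...) {
  if (is.null(object$best)) return(NULL)
  object$best$params
}

#' @export
logLik.bmd_fit <- function(object, ...) {
  if (is.null(object$best)) return(NA_real_)
  structure(object$best$loglik, df = object$best$npar + 1, class = "logLik")
}

#' @export
predict.bmd_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$best)) stop("no eligible model")
  d <- if (is.null(newdata)) object$doses else as.numeric(newdata)
  model_mean_fn(object$best$model, object$best$dir)(object$best$params, d)
}

#' @export
residuals.bmd_fit <- function(object, ...) {
  object$values - stats::predict(object)
}

#' @export
plot.bmd_fit <- function(x, ...) {
  pos <- x$doses[x$doses > 0]
  x0 <- min(pos) / 10
  dplot <- ifelse(x$doses == 0, x0, x$doses)
  graphics::plot(dplot, x$values, log = "x", xlab = "dose (mg/kg/d)",
                 ylab = "log2 expression", ...)
  if (!is.null(x$best)) {
    dd <- exp(seq(log(x0), log(max(x$doses)), length.out = 200))
    graphics::lines(dd, stats::predict(x, dd), col = "steelblue", lwd = 2)
    if (is.finite(x$bmd))
      graphics::abline(v = x$bmd, lty = 2, col = "firebrick")
  }
  invisible(x)
}

#' Run the per-probeset BMD analysis for a study
#'
#' For each prefiltered probeset: fit all eight models, select the best one,
#' compute BMD/BMDL/BMDU at the 1-SD benchmark response, and drop records
#' with BMD above the highest tested dose, BMDU/BMDL ratio above the filter
#' threshold, or no eligible model.
#'
#' @param study a [dose_response_study()].
#' @param prefilter_ids probeset ids that passed the prefilter (subset of
#'   the study's probesets).
#' @param filters a [bmd_filter_params()]; defaults to the study's highest
#'   dose and a ratio of 40.
#' @param control_sd passed to [fit_bmd()].
#' @return data frame with one row per surviving probeset: `probeset_id`,
#'   `model`, `bmd`, `bmdl`, `bmdu`, `aic`, `fit_pvalue`, `flagged`,
#'   `sigma`.
#' @export
run_bmd_analysis <- function(study, prefilter_ids,
                             filters = bmd_filter_params(max(study$doses)),
                             control_sd = c("modeled", "empirical")) {
  control_sd <- match.arg(control_sd)
  stopifnot(all(prefilter_ids %in% study$probeset_ids))
  rows <- vector("list", length(prefilter_ids))
  for (i in seq_along(prefilter_ids)) {
    id <- prefilter_ids[i]
    fb <- fit_bmd(study$matrix[id, ], study$doses, control_sd = control_sd)
    if (is.null(fb$best) || !is.finite(fb$bmd)) next
    if (fb$bmd > filters$max_bmd) next
    ratio <- fb$bmdu / fb$bmdl
    if (!is.finite(ratio) || ratio > filters$max_bmdu_bmdl_ratio) next
    rows[[i]] <- data.frame(
      probeset_id = id, model = fb$best$model, bmd = fb$bmd, bmdl = fb$bmdl,
      bmdu = fb$bmdu, aic = fb$best$aic, fit_pvalue = fb$best$fit_pvalue,
      flagged = isTRUE(fb$best$flagged), sigma = fb$best$sigma,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(probeset_id = character(0), model = character(0),
                      bmd = numeric(0), bmdl = numeric(0), bmdu = numeric(0),
                      aic = numeric(0), fit_pvalue = numeric(0),
                      flagged = logical(0), sigma = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
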