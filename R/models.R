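#' Names of the eight continuous dose-response model families
#'
#' Hill, power, linear, second-degree polynomial, and the four exponential
#' forms of the standard continuous benchmark-dose suite.
#'
#' @return character vector of model names.
#' @export
bmd_model_names <- function() {
  c("hill", "power", "linear", "poly2", "exp2", "exp3", "exp4", "exp5")
}

# Mean functions. Parametrizations follow the continuous BMDS forms:
#   hill : g + v d^n / (k^n + d^n)
#   power: g + beta d^delta                  (delta restricted >= 1)
#   linear / poly2: b0 + b1 d (+ b2 d^2)
#   exp2 : a exp(s b d)
#   exp3 : a exp(s (b d)^p)
#   exp4 : a (c - (c - 1) exp(-b d))
#   exp5 : a (c - (c - 1) exp(-(b d)^p))
# s is the adverse direction (+1 up, -1 down), fixed from the data before
# fitting the exponential models; for exp4/exp5 the direction instead
# constrains c (> 1 up, < 1 down).
model_mean_fn <- function(model, dir = 1) {
  switch(model,
    linear = function(th, d) th[1] + th[2] * d,
    poly2 = function(th, d) th[1] + th[2] * d + th[3] * d^2,
    power = function(th, d) th[1] + th[2] * d^th[3],
    hill = function(th, d) th[1] + th[2] * d^th[3] / (th[4]^th[3] + d^th[3]),
    exp2 = function(th, d) th[1] * exp(dir * pmin(th[2] * d, 500)),
    exp3 = function(th, d) th[1] * exp(dir * pmin((th[2] * d)^th[3], 500)),
    exp4 = function(th, d) th[1] * (th[3] - (th[3] - 1) * exp(-th[2] * d)),
    exp5 = function(th, d)
      th[1] * (th[3] - (th[3] - 1) * exp(-(th[2] * d)^th[4])),
    stop("unknown model: ", model))
}

model_par_names <- function(model) {
  switch(model,
    linear = c("b0", "b1"),
    poly2 = c("b0", "b1", "b2"),
    power = c("g", "beta", "delta"),
    hill = c("g", "v", "n", "k"),
    exp2 = c("a", "b"),
    exp3 = c("a", "b", "p"),
    exp4 = c("a", "b", "c"),
    exp5 = c("a", "b", "c", "p"))
}

model_bounds <- function(model, doses, values, dir = 1) {
  D <- max(doses)
  vr <- range(values)
  span <- max(diff(vr), 1e-3)
  big <- 100 * (abs(vr[2]) + span)
  switch(model,
    linear = list(lower = c(-big, -Inf), upper = c(big, Inf)),
    poly2 = list(lower = c(-big, -Inf, -Inf), upper = c(big, Inf, Inf)),
    power = list(lower = c(-big, -Inf, 1), upper = c(big, Inf, 18)),
    hill = list(lower = c(-big, -10 * span, 1, D * 1e-4),
                upper = c(big, 10 * span, 18, D * 100)),
    exp2 = list(lower = c(1e-8, 0), upper = c(big, 200 / D)),
    exp3 = list(lower = c(1e-8, 0, 1), upper = c(big, 200 / D, 18)),
    exp4 = if (dir > 0)
      list(lower = c(1e-8, 1e-9 / D, 1 + 1e-8), upper = c(big, 1e4 / D, 100))
    else
      list(lower = c(1e-8, 1e-9 / D, 1e-6), upper = c(big, 1e4 / D, 1 - 1e-8)),
    exp5 = if (dir > 0)
      list(lower = c(1e-8, 1e-9 / D, 1 + 1e-8, 1),
           upper = c(big, 1e4 / D, 100, 18))
    else
      list(lower = c(1e-8, 1e-9 / D, 1e-6, 1),
           upper = c(big, 1e4 / D, 1 - 1e-8, 18)))
}

# Deterministic multi-start initializations: method-of-moments guesses from
# the group means plus fixed perturbations. A single start with a 250
# iteration cap is fragile for the saturating families.
model_starts <- function(model, doses, values, dir = 1) {
  gm <- group_means(values, doses)
  lev <- sort(unique(doses))
  D <- max(lev)
  pos <- lev[lev > 0]
  m0 <- gm[1]
  mtop <- gm[length(gm)]
  delta <- mtop - m0
  if (abs(delta) < 1e-8) delta <- 1e-8 * dir
  kmid <- exp(mean(log(pos)))
  switch(model,
    linear = list(c(m0, delta / D)),
    poly2 = list(c(m0, delta / D, 0), c(m0, 0, delta / D^2),
                 c(m0, delta / (2 * D), delta / (2 * D^2))),
    power = lapply(c(1, 2, 4), function(dl) c(m0, delta / D^dl, dl)),
    hill = {
      out <- list()
      for (k in c(min(pos), kmid, D)) for (n in c(1, 2))
        out[[length(out) + 1]] <- c(m0, delta * 1.2, n, k)
      out
    },
    exp2 = {
      b0 <- abs(delta) / (max(abs(m0), 1e-3) * D)
      lapply(c(0.25, 1, 3), function(f) c(max(m0, 1e-3), b0 * f))
    },
    exp3 = {
      b0 <- abs(delta) / (max(abs(m0), 1e-3) * D)
      c(lapply(c(0.5, 1, 2), function(f) c(max(m0, 1e-3), b0 * f, 1)),
        list(c(max(m0, 1e-3), b0, 2), c(max(m0, 1e-3), b0, 4)))
    },
    exp4 = {
      cc <- mtop / max(m0, 1e-3)
      cc <- if (dir > 0) max(cc, 1 + 1e-4) else min(max(cc, 1e-4), 1 - 1e-4)
      lapply(c(1, 5, 20, 0.2), function(f) c(max(m0, 1e-3), f / D, cc))
    },
    exp5 = {
      cc <- mtop / max(m0, 1e-3)
      cc <- if (dir > 0) max(cc, 1 + 1e-4) else min(max(cc, 1e-4), 1 - 1e-4)
      c(lapply(c(1, 5, 20), function(f) c(max(m0, 1e-3), f / D, cc, 1)),
        list(c(max(m0, 1e-3), 2 / D, cc, 2),
             c(max(m0, 1e-3), 10 / D, cc, 3)))
    })
}

# Observed adverse direction: sign of the largest group-mean departure from
# control (standard adverse-direction handling for the exponential family).
response_direction <- function(doses, values) {
  gm <- group_means(values, doses)
  d <- gm[-1] - gm[1]
  if (all(d == 0)) 1 else sign(d[which.max(abs(d))])
}

#' Fit one continuous dose-response model by maximum likelihood
#'
#' Normal errors with constant variance are assumed, so the ML estimate of
#' the mean parameters minimizes the residual sum of squares; the optimizer
#' (bounded quasi-Newton) is capped at 250 iterations and started from at
#' least five deterministic initializations (method-of-moments guesses plus
#' fixed perturbations). The power exponent is restricted to >= 1. The
#' goodness-of-fit p-value comes from a likelihood-ratio test against the
#' saturated group-means model.
#'
#' @param model one of [bmd_model_names()].
#' @param doses,values per-sample doses and log2 responses (>= 3 dose
#'   groups).
#' @param dir adverse direction (+1/-1); defaults to the observed direction.
#' @return a list of class `dr_model_fit` with elements `model`, `params`
#'   (named coefficients), `loglik`, `aic`, `fit_pvalue`, `sigma`, `sse`,
#'   `npar` (mean parameters), `dir`, `converged`; or the same structure with
#'   `converged = FALSE` when no start converges.
#' @export
fit_dose_response <- function(model, doses, values,
                              dir = response_direction(doses, values)) {
  stopifnot(model %in% bmd_model_names())
  gi <- group_index(doses)
  if (length(gi$levels) < 3) stop("need at least 3 dose groups")
  N <- length(values)
  G <- length(gi$levels)
  mf <- model_mean_fn(model, dir)
  sse_sat <- sum((values - unlist(lapply(gi$idx, function(ix)
    rep(mean(values[ix]), length(ix))))[order(unlist(gi$idx))])^2)

  if (model %in% c("linear", "poly2")) {
    X <- if (model == "linear") cbind(1, doses) else cbind(1, doses, doses^2)
    cf <- stats::lm.fit(X, values)$coefficients
    cf[is.na(cf)] <- 0
    best <- list(par = unname(cf), value = sum((values - X %*% cf)^2))
  } else {
    bounds <- model_bounds(model, doses, values, dir)
    obj <- function(th) {
      r <- values - mf(th, doses)
      s <- sum(r^2)
      if (!is.finite(s)) 1e30 else s
    }
    best <- NULL
    for (st in model_starts(model, doses, values, dir)) {
      st <- pmin(pmax(st, bounds$lower), bounds$upper)
      fit <- tryCatch(
        stats::optim(st, obj, method = "L-BFGS-B", lower = bounds$lower,
                     upper = bounds$upper, control = list(maxit = 250)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) &&
          (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best))
      return(structure(list(model = model, params = NULL, loglik = -Inf,
                            aic = Inf, fit_pvalue = NA_real_,
                            sigma = NA_real_, sse = Inf,
                            npar = length(model_par_names(model)), dir = dir,
                            converged = FALSE),
                       class = "dr_model_fit"))
  }
  sse <- max(best$value, 1e-300)
  npar <- length(model_par_names(model))
  sigma2 <- sse / N
  loglik <- -N / 2 * (log(2 * pi * sigma2) + 1)
  aic <- 2 * (npar + 1) - 2 * loglik
  df_fit <- G - npar
  fit_p <- if (df_fit >= 1) {
    stat <- max(N * log(sse / max(sse_sat, 1e-300)), 0)
    stats::pchisq(stat, df_fit, lower.tail = FALSE)
  } else NA_real_
  structure(list(model = model,
                 params = stats::setNames(best$par, model_par_names(model)),
                 loglik = loglik, aic = aic, fit_pvalue = fit_p,
                 sigma = sqrt(sigma2), sse = sse, npar = npar, dir = dir,
                 converged = TRUE),
            class = "dr_model_fit")
}

#' @export
print.dr_model_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Dose-response fit (", x$model, "): did not converge\n", sep = "")
    return(invisible(x))
  }
  cat("Dose-response fit:", x$model, "\n")
  print(signif(x$params, 5))
  cat(sprintf("  sigma = %.4g, logLik = %.4g, AIC = %.4g, fit p = %s\n",
              x$sigma, x$loglik, x$aic,
              if (is.na(x$fit_pvalue)) "NA" else signif(x$fit_pvalue, 3)))
  invisible(x)
}

#' Select the best model among converged fits
#'
#' Selection rules: (i) within the polynomial family, the quadratic replaces
#' the linear model only when the nested likelihood-ratio chi-square test has
#' p < 0.05; (ii) Hill fits with half-max dose `k` below one third of the
#' lowest positive dose are flagged; (iii) the best model is the lowest-AIC
#' eligible fit, and when the winner is a flagged Hill, the next-lowest-AIC
#' model whose goodness-of-fit p-value exceeds 0.05 is used instead. AIC ties
#' break toward fewer parameters, then fixed model-order precedence.
#'
#' @param fits list of `dr_model_fit` objects (one per family).
#' @param lowest_positive_dose lowest tested non-zero dose.
#' @param n_obs number of observations (needed for the nested test); taken
#'   from attribute or supplied.
#' @return the selected `dr_model_fit` with logical `flagged` added, or
#'   `NULL` when no model is eligible.
#' @export
select_best_model <- function(fits, lowest_positive_dose, n_obs) {
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(fits) == 0) return(NULL)
  names(fits) <- vapply(fits, `[[`, character(1), "model")
  if (all(c("linear", "poly2") %in% names(fits))) {
    lin <- fits[["linear"]]; p2 <- fits[["poly2"]]
    stat <- max(n_obs * log(lin$sse / p2$sse), 0)
    p_nested <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    drop <- if (p_nested < 0.05) "linear" else "poly2"
    fits[[drop]] <- NULL
  }
  for (nm in names(fits))
    fits[[nm]]$flagged <- nm == "hill" &&
      fits[[nm]]$params[["k"]] < lowest_positive_dose / 3
  ord <- order(vapply(fits, `[[`, numeric(1), "aic"),
               vapply(fits, `[[`, numeric(1), "npar"),
               match(names(fits), bmd_model_names()))
  fits <- fits[ord]
  winner <- fits[[1]]
  if (winner$flagged) {
    ok <- vapply(fits[-1], function(f)
      !isTRUE(f$flagged) && (is.na(f$fit_pvalue) || f$fit_pvalue > 0.05),
      logical(1))
    if (!any(ok)) return(NULL)
    winner <- fits[-1][[which(ok)[1]]]
  }
  winner
}
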