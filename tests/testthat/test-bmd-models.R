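doses4 <- rep(c(0, 10, 100, 1000), each = 3)

test_that("noiseless linear data is recovered exactly", {
  y <- 1 + 0.5 * doses4
  f <- fit_dose_response("linear", doses4, y)
  expect_equal(unname(f$params), c(1, 0.5), tolerance = 1e-6)
})

test_that("noiseless Hill data recovers its generating parameters", {
  mu <- 0 + 2 * doses4^2 / (10^2 + doses4^2)
  set.seed(2)
  y <- mu + rnorm(length(doses4), sd = 1e-7)
  f <- fit_dose_response("hill", doses4, y)
  expect_equal(unname(f$params), c(0, 2, 2, 10), tolerance = 1e-3)
})

test_that("the log-likelihood matches the closed-form normal expression", {
  set.seed(4)
  y <- 8 + rnorm(length(doses4), sd = 0.3)
  f <- fit_dose_response("linear", doses4, y)
  expect_lt(abs(f$params[["b1"]]), 0.01)
  # independent closed form from the lm residual sum of squares
  sse <- sum(residuals(lm(y ~ doses4))^2)
  n <- length(y)
  ll <- -n / 2 * (log(2 * pi * sse / n) + 1)
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  expect_equal(f$aic, 2 * 3 - 2 * ll, tolerance = 1e-6)
})

test_that("AIC bookkeeping holds for every family on one dataset", {
  set.seed(6)
  y <- 8 + 0.001 * doses4 + rnorm(length(doses4), sd = 0.1)
  for (m in bmd_model_names()) {
    f <- fit_dose_response(m, doses4, y)
    expect_true(f$converged, info = m)
    expect_equal(f$aic, 2 * (f$npar + 1) - 2 * f$loglik, info = m)
    expect_gt(f$sigma, 0)
  }
  # power exponent restriction
  fp <- fit_dose_response("power", doses4, y)
  expect_gte(fp$params[["delta"]], 1)
})

test_that("model selection follows the nested polynomial and Hill-flag rules", {
  mk <- function(model, aic, fit_pvalue = 0.5, params = NULL, sse = 1,
                 npar = 2) {
    structure(list(model = model, aic = aic, fit_pvalue = fit_pvalue,
                   params = params, sse = sse, npar = npar, loglik = 0,
                   sigma = 1, dir = 1, converged = TRUE),
              class = "dr_model_fit")
  }
  # nested test p large: linear carries the polynomial family even with a
  # slightly better poly2 AIC
  n_obs <- 12
  sse_lin <- 1.0
  sse_p2 <- sse_lin * exp(-qchisq(0.6, 1) / n_obs)  # nested p = 0.4
  fits <- list(mk("linear", 100, sse = sse_lin),
               mk("poly2", 99, sse = sse_p2, npar = 3),
               mk("power", 101, npar = 3))
  best <- select_best_model(fits, lowest_positive_dose = 10, n_obs = n_obs)
  expect_equal(best$model, "linear")

  # nested test p small: poly2 replaces linear
  sse_p2b <- sse_lin * exp(-qchisq(0.999, 1) / n_obs)
  fits2 <- list(mk("linear", 100, sse = sse_lin),
                mk("poly2", 99, sse = sse_p2b, npar = 3),
                mk("power", 101, npar = 3))
  expect_equal(select_best_model(fits2, 10, n_obs)$model, "poly2")

  # flagged Hill winner falls back to next best with fit p > 0.05
  fits3 <- list(mk("hill", 90, params = c(g = 0, v = 1, n = 1, k = 1),
                   npar = 4),
                mk("power", 95, fit_pvalue = 0.01, npar = 3),
                mk("linear", 96, fit_pvalue = 0.30))
  best3 <- select_best_model(fits3, lowest_positive_dose = 10, n_obs = n_obs)
  expect_equal(best3$model, "linear")  # power skipped: fit p < 0.05

  # unflagged Hill (k >= lowest/3) wins outright
  fits4 <- list(mk("hill", 90, params = c(g = 0, v = 1, n = 1, k = 5),
                   npar = 4),
                mk("linear", 96))
  expect_equal(select_best_model(fits4, 10, n_obs)$model, "hill")

  # single converged model is selected regardless of AIC
  expect_equal(select_best_model(list(mk("exp2", 1e6)), 10, n_obs)$model,
               "exp2")
  # flagged Hill with no eligible fallback -> NULL
  fits5 <- list(mk("hill", 90, params = c(g = 0, v = 1, n = 1, k = 0.1),
                   npar = 4),
                mk("power", 95, fit_pvalue = 0.01, npar = 3))
  expect_null(select_best_model(fits5, 10, n_obs))
})

test_that("closed-form benchmark doses are reproduced to 1e-3", {
  # linear: bmd = sigma / |beta1| = 1 / 0.5
  y_lin <- 1 + 0.5 * doses4
  f_lin <- fit_dose_response("linear", doses4, y_lin)
  ci <- bmd_from_fit(f_lin, doses4, y_lin, control_sd = 1.0)
  expect_equal(unname(ci["bmd"]), 2.0, tolerance = 1e-3)

  # hill: bmd = k (BMR / (v - BMR))^(1/n) = 10 * (0.5/1.5)^(1/2)
  mu <- 2 * doses4^2 / (10^2 + doses4^2)
  set.seed(8)
  y_hill <- mu + rnorm(length(doses4), sd = 1e-7)
  f_hill <- fit_dose_response("hill", doses4, y_hill)
  ci_h <- bmd_from_fit(f_hill, doses4, y_hill, control_sd = 0.5)
  expect_equal(unname(ci_h["bmd"]), 10 * (0.5 / 1.5)^(1 / 2),
               tolerance = 1e-3)
})

test_that("profile limits agree with a dense grid scan of the profile", {
  d <- rep(c(0, 10, 100, 1000), each = 5)
  set.seed(42)
  y <- 8 + 0.001 * d + rnorm(length(d), sd = 0.1)
  f <- fit_dose_response("linear", d, y)
  ci <- bmd_from_fit(f, d, y)
  # oracle: profile the deviance over a dense BMD grid by direct constrained
  # optimization (sigma = |b1| * bmd substituted analytically)
  n <- length(y)
  prof <- function(b) {
    nll <- function(th) {
      s <- abs(th[2]) * b
      if (s <= 0) return(1e30)
      n / 2 * log(2 * pi * s^2) + sum((y - th[1] - th[2] * d)^2) / (2 * s^2)
    }
    -optim(unname(f$params), nll)$value
  }
  bs <- exp(seq(log(ci["bmd"] / 4), log(ci["bmd"] * 4), length.out = 300))
  dev <- vapply(bs, function(b) 2 * (f$loglik - prof(b)), numeric(1))
  lower <- bs[bs < ci["bmd"]]
  upper <- bs[bs > ci["bmd"]]
  lo <- lower[which.min(abs(dev[bs < ci["bmd"]] - 2.706))]
  hi <- upper[which.min(abs(dev[bs > ci["bmd"]] - 2.706))]
  expect_lt(abs(ci["bmdl"] - lo) / lo, 0.01)
  expect_lt(abs(ci["bmdu"] - hi) / hi, 0.01)
  expect_true(ci["bmdl"] <= ci["bmd"] && ci["bmd"] <= ci["bmdu"])
})

test_that("curves that never reach the BMR yield the infinite-BMD sentinel", {
  set.seed(10)
  y <- 8 + 0.00001 * doses4 + rnorm(length(doses4), sd = 0.2)
  f <- fit_dose_response("linear", doses4, y)
  ci <- bmd_from_fit(f, doses4, y, control_sd = 5)
  expect_equal(unname(ci["bmd"]), Inf)
})

test_that("BMD is equivariant under dose rescaling", {
  set.seed(12)
  y <- 8 + 0.002 * doses4 + rnorm(length(doses4), sd = 0.1)
  f1 <- fit_bmd(y, doses4)
  f2 <- fit_bmd(y, doses4 * 10)
  expect_equal(f2$bmd / f1$bmd, 10, tolerance = 1e-3)
  expect_equal(f2$bmdl / f1$bmdl, 10, tolerance = 0.02)
  expect_equal(f2$bmdu / f1$bmdu, 10, tolerance = 0.02)
})

test_that("AIC ordering of the location families is shift invariant", {
  # the exponential families are multiplicative in the response, so only the
  # location families (linear, poly2, power, hill) carry this invariance
  set.seed(14)
  y <- 8 + 0.002 * doses4 + rnorm(length(doses4), sd = 0.1)
  fams <- c("linear", "poly2", "power", "hill")
  a1 <- vapply(fams, function(m) fit_dose_response(m, doses4, y)$aic,
               numeric(1))
  a2 <- vapply(fams, function(m) fit_dose_response(m, doses4, y + 7)$aic,
               numeric(1))
  expect_equal(order(a1), order(a2))
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("bmd_fit methods behave like a classed model object", {
  set.seed(16)
  y <- 8 + 0.002 * doses4 + rnorm(length(doses4), sd = 0.1)
  f <- fit_bmd(y, doses4)
  expect_s3_class(f, "bmd_fit")
  expect_true(is.numeric(coef(f)))
  expect_equal(length(predict(f)), length(y))
  expect_equal(predict(f, c(0, 50)), predict(f, c(0, 50)))
  expect_equal(residuals(f), y - predict(f))
  expect_equal(as.numeric(logLik(f)), f$best$loglik)
  expect_output(print(f), "BMD")
  expect_output(print(summary(f)), "AIC")
})

test_that("run_bmd_analysis applies the BMD sanity filters", {
  fix <- small_pipeline_fixture()
  rec <- fix$records
  expect_true(all(rec$bmdl <= rec$bmd + 1e-9))
  expect_true(all(rec$bmd <= rec$bmdu + 1e-9))
  expect_true(all(rec$bmd <= max(fix$sim$study$doses)))
  expect_true(all(rec$bmdu / rec$bmdl <= 40))
  # a tiny max_bmd removes everything
  none <- run_bmd_analysis(fix$sim$study, fix$passing[1:3],
                           bmd_filter_params(max_bmd = 1e-6))
  expect_equal(nrow(none), 0)
  # a ratio threshold just below an observed ratio drops that record
  r1 <- rec$bmdu[1] / rec$bmdl[1]
  one <- run_bmd_analysis(fix$sim$study, rec$probeset_id[1],
                          bmd_filter_params(max(fix$sim$study$doses),
                                            max_bmdu_bmdl_ratio = r1 * 0.99))
  expect_equal(nrow(one), 0)
})

test_that("estimated BMDs recover the synthetic truth on the small study", {
  fix <- small_pipeline_fixture()
  m <- merge(fix$records, fix$sim$truth, by = "probeset_id")
  expect_gt(nrow(m), 30)
  err <- abs(log10(m$bmd) - log10(m$true_bmd))
  expect_lte(median(err), log10(2))  # small-n study; the standard study is
                                     # held to log10(1.5) in the acceptance
                                     # suite
})
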