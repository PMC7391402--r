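test_that("placebo effect follows the Weibull-with-drift form", {
  p <- long_params(baseline = 0, pmax = -1.22, tprog = 16.2, drug = 0)
  expect_equal(placebo_effect(0, p), 0)
  # half-life definition: exponential model reaches Pmax/2 at Tprog
  expect_equal(placebo_effect(16.2, p), -0.61, tolerance = 1e-12)
  # drift adds linearly
  pd <- p; pd$drift <- 0.05
  expect_equal(placebo_effect(10, pd), placebo_effect(10, p) + 0.5)
  expect_error(placebo_effect(-1, p), "non-negative")
  # Weibull exponent 1 reproduces the exponential model exactly
  pw <- p; pw$wei <- 1
  t <- seq(0, 6, 0.1)
  expect_identical(placebo_effect(t, pw), placebo_effect(t, p))
  manual <- -1.22 * (1 - exp(-log(2) / 16.2 * t))
  expect_equal(placebo_effect(t, p), manual, tolerance = 1e-15)
  # Weibull shape changes the approach but not the endpoints
  ps <- p; ps$wei <- 1.6
  expect_equal(placebo_effect(0, ps), 0)
  expect_lt(abs(placebo_effect(300, ps) - ps$pmax), 1e-6)
})

test_that("disability composes baseline, placebo, drug and covariates", {
  p <- long_params(baseline = -0.0993, pmax = -1.22, tprog = 0.54,
                   drug = -0.565)
  expect_equal(disability(0, 0, p)[1, 1], -0.0993)
  # identical offset at any nonzero dose
  expect_equal(disability(c(1, 3, 6), 20, p), disability(c(1, 3, 6), 30, p))
  # drug applies only post-dose
  expect_equal(disability(0, 30, p)[1, 1], disability(0, 0, p)[1, 1])
  expect_equal(disability(3, 30, p)[1, 1] - disability(3, 0, p)[1, 1],
               -0.565)
  # additive PVR effect on baseline: +100 mL above center shifts +0.327
  pc <- p
  pc$covariates <- data.frame(parameter = "baseline", covariate = "PVR",
                              form = "additive", coef = 0.00327, center = 50)
  expect_equal(disability(0, 0, pc, covariates = list(PVR = 150))[1, 1],
               -0.0993 + 0.327, tolerance = 1e-12)
  expect_error(disability(0, 0, pc, covariates = list(AGE = 70)),
               "unknown covariate")
  # random effects enter where they should
  eta <- list(baseline = 0.5, pmax = 0, drift = 0, log_tprog = 0)
  expect_equal(disability(0, 0, p, eta = eta)[1, 1], -0.0993 + 0.5)
})

test_that("Laplace joint OFV matches brute-force 4-D integration", {
  icc <- ref_icc()[c("IPSS1", "QoL")]
  p <- long_params(baseline = -0.1, pmax = -1.0, tprog = 0.6, drug = -0.5)
  re <- re_spec(sd_baseline = 0.9, sd_pmax = 0.7, sd_drift = 0.05,
                sd_tprog = 0.3,
                corr = list(baseline_pmax = 0.2, pmax_drift = 0.3))
  set.seed(31)
  rows <- list()
  for (i in 1:3) {
    dose <- c(0, 20, 30)[i]
    for (v in 1:2) for (it in icc)
      rows[[length(rows) + 1]] <- data.frame(
        ID = i, TIME = c(0, 3)[v], VISIT = v, DOSE = dose, ITEM = it$item,
        DV = grm_sample_score(it, rnorm(1, if (v == 1) 0 else -1.5, 1.2)))
  }
  ds <- as_pro_dataset(do.call(rbind, rows))
  ofv_lap <- joint_ofv(ds, icc, p, re)
  ofv_bf <- brute_long_ofv(ds, icc, p, re, ngrid = 17, width = 4.5)
  expect_lt(abs(ofv_lap - ofv_bf), 0.5)
})

test_that("zero-variance random effects give the exact fixed likelihood", {
  icc <- ref_icc()[c("IPSS1", "IPSS7")]
  p <- long_params(baseline = -0.2, pmax = -0.8, tprog = 0.5, drug = -0.4)
  re0 <- re_spec(sd_baseline = 0, sd_pmax = 0, sd_drift = 0, sd_tprog = 0)
  ds <- small_trial(n = 10, seed = 37)
  ds <- ds[ds$ITEM %in% names(icc), ]
  ofv <- joint_ofv(ds, icc, p, re0)
  # direct fixed-effects likelihood
  ll <- 0
  for (r in seq_len(nrow(ds))) {
    psi <- disability(ds$TIME[r], ds$DOSE[r], p)[1, 1]
    it <- icc[[ds$ITEM[r]]]
    ll <- ll + log(grm_category_probs(it, psi)[1, ds$DV[r] + 1])
  }
  expect_equal(ofv, -2 * as.numeric(ll), tolerance = 1e-8)
  # drug value is irrelevant on placebo-only data
  plc <- ds[ds$DOSE == 0, ]
  p0 <- p; p0$drug <- 0
  expect_equal(joint_ofv(plc, icc, p, re0), joint_ofv(plc, icc, p0, re0),
               tolerance = 1e-10)
})

test_that("independent subjects contribute additively to the OFV", {
  icc <- ref_icc()[c("IPSS2", "QoL")]
  p <- long_params(baseline = 0, pmax = -1, tprog = 0.6, drug = -0.5)
  re <- re_spec(sd_baseline = 1, sd_pmax = 0.8, sd_drift = 1e-4,
                sd_tprog = 0.3)
  ds <- small_trial(n = 6, seed = 41)
  ds <- ds[ds$ITEM %in% names(icc), ]
  dup <- ds
  dup$ID <- dup$ID + 1000L
  both <- as_pro_dataset(rbind(as.data.frame(ds), as.data.frame(dup)))
  expect_equal(joint_ofv(both, icc, p, re), 2 * joint_ofv(ds, icc, p, re),
               tolerance = 1e-6)
})

test_that("drug effect estimation detects a simulated effect via the LRT", {
  ref <- ref_long()
  p <- ref$params; p$covariates <- NULL
  ds <- small_trial(n = 120, seed = 43)
  fitF <- fit_longitudinal(ds, ref_icc(), p, ref$re,
                           control = list(rel.tol = 1e-5))
  pw <- fitF$params; pw$drug <- 0
  fitR <- fit_longitudinal(ds, ref_icc(), pw, fitF$re, include_drug = FALSE,
                           control = list(rel.tol = 1e-5))
  expect_gt(fitR$ofv - fitF$ofv, 3.84)
  # the drug estimate carries the right sign and magnitude
  expect_lt(fitF$params$drug, -0.2)
  expect_gt(fitF$params$drug, -1.2)
})

test_that("co-estimating ICCs can only improve the OFV", {
  ref <- ref_long()
  p <- ref$params; p$covariates <- NULL
  icc3 <- ref_icc()[c("IPSS1", "IPSS4", "QoL")]
  ds <- small_trial(n = 30, seed = 47)
  ds <- ds[ds$ITEM %in% names(icc3), ]
  ctl <- list(rel.tol = 1e-6, iter.max = 300)
  fit_fix <- fit_longitudinal(ds, icc3, p, ref$re, control = ctl)
  fit_co <- fit_longitudinal(ds, icc3, fit_fix$params, fit_fix$re,
                             co_estimate_icc = TRUE, control = ctl)
  expect_lte(fit_co$ofv, fit_fix$ofv + 1e-3)
})

test_that("stepwise covariate modeling includes real and skips null effects", {
  ref <- ref_long()
  icc4 <- ref_icc()[c("IPSS1", "IPSS2", "IPSS5", "QoL")]
  # simulate with a strong PVR effect on baseline
  p <- ref$params
  p$covariates$coef <- 0.01
  ds <- simulate_trial(trial_design(n_subjects = 100), ref_icc(), p,
                       ref$re, seed = 53)
  ds <- ds[ds$ITEM %in% names(icc4), ]
  cands <- data.frame(parameter = c("baseline", "pmax"),
                      covariate = "PVR",
                      form = c("additive", "multiplicative"))
  p0 <- ref$params; p0$covariates <- NULL
  res <- scm(ds, icc4, p0, ref$re, cands,
             control = list(rel.tol = 1e-5, iter.max = 120))
  expect_true(nrow(res$included) >= 1)
  expect_true("baseline" %in% res$included$parameter)
  expect_equal(res$log$step[1], "forward")
  cf <- res$fit$params$covariates
  expect_gt(cf$coef[cf$parameter == "baseline"], 0)

  # with no simulated effect the final set is empty
  pn <- ref$params; pn$covariates <- NULL
  dsn <- simulate_trial(trial_design(n_subjects = 60), ref_icc(), pn,
                        ref$re, seed = 59)
  dsn <- dsn[dsn$ITEM %in% names(icc4), ]
  resn <- scm(dsn, icc4, p0, ref$re, cands,
              control = list(rel.tol = 1e-5, iter.max = 120))
  expect_equal(nrow(resn$included), 0)
})
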