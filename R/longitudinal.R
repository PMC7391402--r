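#' Longitudinal latent-disability model parameters
#'
#' Fixed effects of the latent trajectory model
#' `Disability(t) = Baseline + Placebo(t) + Drug`, with
#' `Placebo(t) = Pmax (1 - exp(-((ln 2 / Tprog) t)^WEI)) + Drift t` and an
#' offset drug effect applied identically at every nonzero dose (no
#' dose-response).  `WEI = 1` gives the exponential placebo model; the
#' bidimensional model carries one parameter set per latent dimension
#' (voiding, storage) with a shared Weibull exponent.
#'
#' @param baseline Population baseline disability (length = dimensions).
#' @param pmax Maximal placebo response.
#' @param tprog Placebo half-life, in the dataset's time unit (months).
#' @param drug Offset drug effect (0 for a no-drug model).
#' @param drift Linear relapse/remission drift per time unit (shared).
#' @param wei Weibull exponent (shared; 1 = exponential).
#' @param covariates Optional data frame (parameter, covariate, form, coef,
#'   center) of covariate effects; `form` is `"additive"` or
#'   `"multiplicative"`.
#' @return A `long_params` object.
#' @export
long_params <- function(baseline, pmax, tprog, drug = rep(0, length(baseline)),
                        drift = 0, wei = 1, covariates = NULL) {
  m <- length(baseline)
  stopifnot(length(pmax) == m, length(tprog) == m, length(drug) == m,
            all(tprog > 0), wei > 0)
  structure(list(m = m, baseline = unname(baseline), pmax = unname(pmax),
                 tprog = unname(tprog), drug = unname(drug),
                 drift = unname(drift), wei = unname(wei),
                 covariates = covariates),
            class = "long_params")
}

#' Between-subject variability specification
#'
#' Random effects are normal for Baseline (one per dimension), Pmax and
#' Drift, and lognormal for Tprog (normal on log Tprog).  Only the named
#' correlations are nonzero; the implied covariance matrix is kept positive
#' semi-definite by construction (Cholesky-factor parameterization in the
#' fitting backend).
#'
#' @param sd_baseline SD(s) of the baseline random effect (latent units).
#' @param sd_pmax,sd_drift SDs of the Pmax and Drift random effects.
#' @param sd_tprog SD of log Tprog.
#' @param corr Named list of correlations; recognized names:
#'   `baseline_pmax`, `pmax_drift` (unidimensional), `baseline_v_s`
#'   (bidimensional).
#' @return A `re_spec` object.
#' @export
re_spec <- function(sd_baseline, sd_pmax, sd_drift, sd_tprog, corr = list()) {
  structure(list(sd_baseline = unname(sd_baseline), sd_pmax = unname(sd_pmax),
                 sd_drift = unname(sd_drift), sd_tprog = unname(sd_tprog),
                 corr = corr),
            class = "re_spec")
}

# random-effect order used throughout: baseline_1..m, pmax, drift, log tprog
.re_sds <- function(re, m) {
  c(re$sd_baseline, re$sd_pmax, re$sd_drift, re$sd_tprog)
}

# correlation matrix implied by the sparse correlation list
.re_corr <- function(re, m) {
  n <- m + 3
  C <- diag(n)
  i_pmax <- m + 1; i_drift <- m + 2
  if (!is.null(re$corr$baseline_pmax) && m == 1)
    C[1, i_pmax] <- C[i_pmax, 1] <- re$corr$baseline_pmax
  if (!is.null(re$corr$pmax_drift))
    C[i_pmax, i_drift] <- C[i_drift, i_pmax] <- re$corr$pmax_drift
  if (!is.null(re$corr$baseline_v_s) && m == 2)
    C[1, 2] <- C[2, 1] <- re$corr$baseline_v_s
  C
}

.re_cov <- function(re, m) {
  sds <- .re_sds(re, m)
  S <- diag(sds, length(sds)) %*% .re_corr(re, m) %*% diag(sds, length(sds))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("random-effects covariance is not PSD")
  S
}

#' Placebo effect over time
#'
#' `Placebo(t) = Pmax (1 - exp(-((ln 2 / Tprog) t)^WEI)) + Drift t`; with
#' `WEI = 1` this is the exponential model with half-life `Tprog`, so
#' `Placebo(Tprog) = Pmax / 2` when `Drift = 0`.
#'
#' @param t Time(s) since dosing, non-negative, in the dataset time unit.
#' @param p A [long_params()] object.
#' @param dim Latent dimension (for bidimensional parameters).
#' @return Placebo effect values; `placebo_effect(0, p)` is 0.
#' @export
placebo_effect <- function(t, p, dim = 1L) {
  if (any(t < 0)) stop("time must be non-negative")
  lam <- log(2) / p$tprog[dim]
  p$pmax[dim] * (1 - exp(-(lam * t)^p$wei)) + p$drift * t
}

#' Latent disability for a subject
#'
#' `Disability = Baseline + Placebo + Drug` with subject-level random
#' effects and additive/multiplicative covariate adjustments.  The drug
#' offset applies at post-dose times for any nonzero dose; at baseline
#' (`t = 0`) disability equals the individual baseline.
#'
#' @param t Time(s) since dosing.
#' @param dose Dose in mg (0 = placebo).
#' @param p A [long_params()] object.
#' @param eta Named list/vector of subject random effects: `baseline`
#'   (length = dimensions), `pmax`, `drift`, `log_tprog`; defaults to zero.
#' @param covariates Named list/vector of the subject's covariate values;
#'   required when `p$covariates` is non-empty.
#' @return A matrix with one row per time and one column per latent
#'   dimension.
#' @export
disability <- function(t, dose, p, eta = NULL, covariates = NULL) {
  if (any(t < 0)) stop("time must be non-negative")
  m <- p$m
  if (is.null(eta))
    eta <- list(baseline = rep(0, m), pmax = 0, drift = 0, log_tprog = 0)
  base <- p$baseline
  pmax <- p$pmax
  drug <- p$drug
  if (!is.null(p$covariates) && nrow(p$covariates) > 0) {
    for (i in seq_len(nrow(p$covariates))) {
      cv <- p$covariates[i, ]
      if (is.null(covariates) || is.null(covariates[[cv$covariate]]))
        stop("unknown covariate: ", cv$covariate)
      z <- covariates[[cv$covariate]] - cv$center
      d <- if (!is.null(cv$dim) && !is.na(cv$dim)) cv$dim else 1L
      if (cv$parameter == "baseline") {
        if (cv$form == "additive") base[d] <- base[d] + cv$coef * z
        else base[d] <- base[d] * (1 + cv$coef * z)
      } else if (cv$parameter == "pmax") {
        pmax[d] <- pmax[d] * (1 + cv$coef * z)
      } else if (cv$parameter == "drug") {
        drug[d] <- drug[d] * (1 + cv$coef * z)
      } else stop("unknown covariate target: ", cv$parameter)
    }
  }
  out <- matrix(0, length(t), m)
  for (d in seq_len(m)) {
    lam <- log(2) / (p$tprog[d] * exp(eta$log_tprog))
    pl <- (pmax[d] + eta$pmax) * (1 - exp(-(lam * t)^p$wei)) +
      (p$drift + eta$drift) * t
    out[, d] <- base[d] + eta$baseline[d] + ifelse(t > 0, pl, 0) +
      ifelse(t > 0 & dose > 0, drug[d], 0)
  }
  out
}
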