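# Longitudinal-stage TMB machinery.

# assemble the TMB data/parameter/map lists for the longitudinal model
.long_setup <- function(ds, icc, p, re, include_drug = TRUE,
                        estimate_drift = FALSE, estimate_wei = NULL,
                        co_estimate_icc = FALSE) {
  m <- p$m
  if (attr(icc, "n_dim") != m)
    stop("latent dimensions of ICC set and longitudinal parameters differ")
  if (is.null(estimate_wei)) estimate_wei <- p$wei != 1

  icc <- icc[intersect(names(icc), unique(ds$ITEM))]
  class(icc) <- "icc_params"
  ds <- ds[ds$ITEM %in% names(icc), , drop = FALSE]
  ids <- unique(ds$ID)
  subj <- match(ds$ID, ids)
  trt <- as.integer(tapply(ds$DOSE > 0, factor(ds$ID, levels = ids), any))

  # covariate effects
  cov <- p$covariates
  n_cov <- if (is.null(cov)) 0L else nrow(cov)
  zcov <- matrix(0, length(ids), max(n_cov, 0))
  cov_target <- cov_form <- cov_dim <- integer(0)
  cov_coef <- numeric(0)
  if (n_cov > 0) {
    for (i in seq_len(n_cov)) {
      cname <- cov$covariate[i]
      if (!cname %in% names(ds)) stop("unknown covariate: ", cname)
      vals <- tapply(ds[[cname]], factor(ds$ID, levels = ids), function(x) x[1])
      center <- cov$center[i]
      if (is.null(center) || is.na(center)) center <- median(vals)
      cov$center[i] <- center
      zcov[, i] <- vals - center
    }
    cov_target <- match(cov$parameter, c("baseline", "pmax", "drug")) - 1L
    cov_form <- as.integer(cov$form == "multiplicative")
    cov_dim <- if (!is.null(cov$dim)) as.integer(cov$dim) - 1L else
      rep(0L, n_cov)
    cov_coef <- cov$coef
  }

  n_re <- m + 3L
  sds <- .re_sds(re, m)
  no_re <- all(sds == 0)
  Lmask <- matrix(0L, n_re, n_re)
  ltheta <- numeric(0)
  toL <- function(r) r / sqrt(1 - r^2)
  if (!no_re) {
    if (m == 1 && !is.null(re$corr$baseline_pmax)) {
      Lmask[m + 1L, 1L] <- 1L
      ltheta <- c(ltheta, toL(re$corr$baseline_pmax))
    }
    if (m == 2 && !is.null(re$corr$baseline_v_s)) {
      Lmask[2L, 1L] <- 1L
      ltheta <- c(ltheta, toL(re$corr$baseline_v_s))
    }
    if (!is.null(re$corr$pmax_drift)) {
      Lmask[m + 2L, m + 1L] <- 1L
      ltheta <- c(ltheta, toL(re$corr$pmax_drift))
    }
  }

  arr <- .item_arrays(icc)
  data <- c(list(model = 2L, m = m,
                 obs_unit = subj - 1L,
                 obs_item = match(ds$ITEM, names(icc)) - 1L,
                 obs_y = ds$DV,
                 obs_time = ds$TIME,
                 obs_post = as.integer(ds$TIME > 0),
                 trt = trt, zcov = zcov,
                 cov_target = cov_target, cov_form = cov_form,
                 cov_dim = cov_dim,
                 no_re = as.integer(no_re), Lmask = Lmask),
            arr)
  parameters <- c(.item_pars(icc),
                  list(base = p$baseline, pmax = p$pmax,
                       log_tprog = log(p$tprog),
                       drug = if (include_drug) p$drug else rep(0, m),
                       drift = p$drift, log_wei = log(p$wei),
                       cov_coef = cov_coef,
                       log_sd = log(pmax(sds, 1e-8)),
                       ltheta = ltheta,
                       eta = matrix(0, length(ids), n_re)))
  map <- list()
  if (!co_estimate_icc) {
    ip <- .item_pars(icc)
    map$log_a <- .map_off(ip$log_a)
    map$B1 <- .map_off(ip$B1)
    map$log_dB <- .map_off(ip$log_dB)
  }
  if (!include_drug) map$drug <- .map_off(numeric(m))
  if (!estimate_drift) map$drift <- factor(NA)
  if (!estimate_wei) map$log_wei <- factor(NA)
  if (no_re) {
    map$log_sd <- .map_off(numeric(n_re))
    map$ltheta <- .map_off(ltheta)
    map$eta <- .map_off(parameters$eta)
  }
  list(data = data, parameters = parameters, map = map,
       random = if (no_re) NULL else "eta",
       ids = ids, m = m, cov = cov, icc = icc, no_re = no_re)
}

#' Joint objective function value of the longitudinal latent model
#'
#' Evaluates `-2 log` marginal likelihood of the longitudinal model at fixed
#' parameter values: per-subject random effects (Baseline, Pmax, Drift,
#' log Tprog) are integrated out by the Laplace approximation, with item
#' likelihoods from fixed ICCs.  With an all-zero [re_spec()] the random
#' effects drop out and the value is the exact fixed-effects likelihood.
#'
#' @param ds A `pro_dataset`.
#' @param icc Fixed `icc_params`.
#' @param p A [long_params()] object.
#' @param re A [re_spec()] object.
#' @return The OFV (a scalar), deterministic given data and parameters.
#' @export
joint_ofv <- function(ds, icc, p, re) {
  s <- .long_setup(ds, icc, p, re)
  # no optimization happens: the objective is simply evaluated at the
  # supplied parameter values (the setup's own maps fix eta when there are
  # no random effects)
  s$map$log_sd <- NULL; s$map$ltheta <- NULL
  if (s$no_re) s$map$eta <- .map_off(s$parameters$eta)
  obj <- TMB::MakeADFun(data = s$data, parameters = s$parameters,
                        map = s$map, random = s$random, DLL = "proirt",
                        silent = TRUE)
  v <- obj$fn(obj$par)
  if (!is.finite(v)) stop("non-finite joint objective")
  2 * as.numeric(v)
}

#' Fit the longitudinal latent-disability model
#'
#' Stage 2: minimizes the Laplace-approximated `-2 log` marginal likelihood
#' over the trajectory fixed effects and between-subject variability, with
#' the ICCs fixed at their stage-1 estimates (or co-estimated).
#'
#' @inheritParams joint_ofv
#' @param start Starting [long_params()]; also defines the covariate model
#'   (covariate rows with `center = NA` are centered at the dataset median).
#' @param re_start Starting [re_spec()]; its correlation names define which
#'   correlations are estimated (others are fixed to zero).
#' @param include_drug If `FALSE` the drug effect is fixed to zero (the
#'   reduced model of the likelihood-ratio test).
#' @param estimate_drift Estimate a population drift (default: fixed at
#'   `start$drift`).
#' @param estimate_wei Estimate the Weibull exponent; default only when the
#'   starting value differs from 1.
#' @param co_estimate_icc Also re-estimate the ICC parameters.
#' @param fix_variance Keep the between-subject SDs and correlations fixed
#'   at their starting values (useful as a fast first stage whose estimates
#'   warm-start the full optimization).
#' @param se Attempt standard errors via [TMB::sdreport()]; failure is a
#'   warning, not an error.
#' @param control Passed to [stats::nlminb()].
#' @return A `long_fit` object with elements `params`, `re`, `ofv`,
#'   `convergence`, `eta` (posterior-mode random effects), and optional `se`.
#' @export
fit_longitudinal <- function(ds, icc, start, re_start, include_drug = TRUE,
                             estimate_drift = FALSE, estimate_wei = NULL,
                             co_estimate_icc = FALSE, fix_variance = FALSE,
                             se = FALSE, control = list()) {
  s <- .long_setup(ds, icc, start, re_start, include_drug = include_drug,
                   estimate_drift = estimate_drift,
                   estimate_wei = estimate_wei,
                   co_estimate_icc = co_estimate_icc)
  if (fix_variance && !s$no_re) {
    s$map$log_sd <- .map_off(s$parameters$log_sd)
    s$map$ltheta <- .map_off(s$parameters$ltheta)
  }
  obj <- TMB::MakeADFun(data = s$data, parameters = s$parameters,
                        map = s$map, random = s$random, DLL = "proirt",
                        silent = TRUE)
  best <- new.env(); best$val <- Inf; best$par <- obj$par
  fn <- function(par) {
    v <- tryCatch(as.numeric(obj$fn(par)), error = function(e) NA_real_)
    if (!is.finite(v)) return(1e10)
    if (v < best$val) { best$val <- v; best$par <- par }
    v
  }
  gr <- function(par) {
    g <- tryCatch(obj$gr(par), error = function(e) NULL)
    if (is.null(g) || any(!is.finite(g))) rep(0, length(par)) else g
  }
  nm <- names(obj$par)
  lower <- rep(-Inf, length(obj$par)); upper <- rep(Inf, length(obj$par))
  lower[nm == "log_sd"] <- log(1e-8); upper[nm == "log_sd"] <- 3
  lower[nm == "log_tprog"] <- log(0.01); upper[nm == "log_tprog"] <- log(500)
  lower[nm == "ltheta"] <- -20; upper[nm == "ltheta"] <- 20
  lower[nm == "log_wei"] <- log(0.2); upper[nm == "log_wei"] <- log(5)
  ctrl <- modifyList(list(iter.max = 400, eval.max = 800, rel.tol = 1e-9),
                     control)
  opt <- nlminb(obj$par, fn, gr, lower = lower, upper = upper, control = ctrl)
  if (!is.finite(best$val))
    stop("longitudinal estimation failed; best-so-far objective non-finite")

  pl <- obj$env$parList()
  m <- s$m
  cov_out <- s$cov
  if (!is.null(cov_out) && nrow(cov_out) > 0) cov_out$coef <- pl$cov_coef
  pars <- long_params(baseline = pl$base, pmax = pl$pmax,
                      tprog = exp(pl$log_tprog),
                      drug = if (include_drug) pl$drug else rep(0, m),
                      drift = pl$drift, wei = exp(pl$log_wei),
                      covariates = cov_out)
  sds <- exp(pl$log_sd)
  fromL <- function(t) t / sqrt(1 + t^2)
  corr <- list()
  if (!s$no_re) {
    lt <- pl$ltheta; k <- 1
    if (m == 1 && !is.null(re_start$corr$baseline_pmax)) {
      corr$baseline_pmax <- fromL(lt[k]); k <- k + 1
    }
    if (m == 2 && !is.null(re_start$corr$baseline_v_s)) {
      corr$baseline_v_s <- fromL(lt[k]); k <- k + 1
    }
    if (!is.null(re_start$corr$pmax_drift)) corr$pmax_drift <- fromL(lt[k])
  }
  re <- re_spec(sd_baseline = sds[seq_len(m)], sd_pmax = sds[m + 1],
                sd_drift = sds[m + 2], sd_tprog = sds[m + 3], corr = corr)
  fit <- list(params = pars, re = re, ofv = 2 * best$val,
              convergence = opt$convergence, message = opt$message,
              iterations = opt$iterations, ids = s$ids,
              eta = if (s$no_re) NULL else obj$env$parList()$eta,
              include_drug = include_drug, structure_dims = m)
  if (se) {
    rep <- tryCatch(TMB::sdreport(obj, par.fixed = best$par),
                    error = function(e) NULL)
    ok <- !is.null(rep) && all(is.finite(summary(rep, "fixed")[, 2]))
    if (!ok) warning("could not produce standard errors (unstable Hessian)")
    else {
      sm <- summary(rep, select = "report")
      fit$se <- data.frame(parameter = rownames(sm), estimate = sm[, 1],
                           se = sm[, 2], rse = 100 * abs(sm[, 2] / sm[, 1]),
                           row.names = NULL)
    }
  }
  class(fit) <- "long_fit"
  fit
}

#' @export
#' @method print long_fit
print.long_fit <- function(x, ...) {
  p <- x$params
  cat("Longitudinal latent-disability fit (", p$m, " dimension(s)): OFV = ",
      round(x$ofv, 2), "\n", sep = "")
  cat("  baseline:", signif(p$baseline, 3), " pmax:", signif(p$pmax, 3),
      " tprog:", signif(p$tprog, 3), " drug:", signif(p$drug, 3),
      " wei:", signif(p$wei, 3), "\n")
  invisible(x)
}

#' Stepwise covariate modeling
#'
#' Forward inclusion / backward elimination by likelihood-ratio criteria on
#' the longitudinal model OFV: a candidate enters when its inclusion drops
#' the OFV by more than `qchisq(0.99, 1) = 6.63` (p = 0.01) and survives
#' elimination only if its removal raises the OFV by at least
#' `qchisq(0.999, 1) = 10.83` (p = 0.001).  Ties are broken by candidate
#' order and the decision path is logged.
#'
#' @inheritParams fit_longitudinal
#' @param candidates Data frame of candidate effects with columns
#'   `parameter` (`baseline`, `pmax`, `drug`), `covariate` (a dataset
#'   column) and `form` (`additive`/`multiplicative`).
#' @param forward_dofv,backward_dofv LRT thresholds on the OFV drop.
#' @return A list: `fit` (final model), `included` (retained candidate
#'   rows), `log` (step-by-step data frame).
#' @export
scm <- function(ds, icc, start, re_start, candidates,
                forward_dofv = qchisq(0.99, 1),
                backward_dofv = qchisq(0.999, 1), ...) {
  fit_with <- function(rows) {
    cov <- if (length(rows) == 0) NULL else {
      cc <- candidates[rows, , drop = FALSE]
      cc$coef <- 0; cc$center <- NA_real_
      cc
    }
    p <- start; p$covariates <- cov
    fit_longitudinal(ds, icc, p, re_start, ...)
  }
  log <- list()
  included <- integer(0)
  base_fit <- fit_with(included)
  repeat { # forward
    remaining <- setdiff(seq_len(nrow(candidates)), included)
    if (length(remaining) == 0) break
    dofv <- vapply(remaining, function(r) {
      f <- tryCatch(fit_with(c(included, r)), error = function(e) NULL)
      if (is.null(f)) -Inf else base_fit$ofv - f$ofv
    }, 0)
    bestr <- remaining[which.max(dofv)]
    log[[length(log) + 1]] <- data.frame(
      step = "forward", parameter = candidates$parameter[bestr],
      covariate = candidates$covariate[bestr], dofv = max(dofv),
      action = if (max(dofv) > forward_dofv) "included" else "stopped")
    if (max(dofv) <= forward_dofv) break
    included <- c(included, bestr)
    base_fit <- fit_with(included)
  }
  repeat { # backward
    if (length(included) == 0) break
    dofv <- vapply(included, function(r) {
      f <- fit_with(setdiff(included, r))
      f$ofv - base_fit$ofv # OFV increase caused by removal
    }, 0)
    worst <- which.min(dofv)
    log[[length(log) + 1]] <- data.frame(
      step = "backward", parameter = candidates$parameter[included[worst]],
      covariate = candidates$covariate[included[worst]], dofv = min(dofv),
      action = if (min(dofv) < backward_dofv) "eliminated" else "retained")
    if (min(dofv) >= backward_dofv) break
    included <- included[-worst]
    base_fit <- fit_with(included)
  }
  list(fit = base_fit,
       included = candidates[included, , drop = FALSE],
       log = do.call(rbind, log))
}
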