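# Stage 3: simulation-based power, type-I error and predictive checks.

# deterministic per-replicate seeds below 2^31 derived from a master seed
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1, n)
}

.logit <- function(p) qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6))

# interpolate the sample size reaching `target` power: monotone (isotonic)
# piecewise-linear interpolation on the logit-power scale
.interp_n <- function(n, power, target = 0.8) {
  o <- order(n)
  n <- n[o]
  iso <- isoreg(n, power[o])
  p <- iso$yf
  if (all(p < target) || all(p > target)) return(NA_real_)
  lp <- .logit(p); lt <- .logit(target)
  i <- max(which(lp <= lt))
  if (lp[i] == lt) return(n[i])
  if (i == length(n)) return(n[i])
  n[i] + (n[i + 1] - n[i]) * (lt - lp[i]) / (lp[i + 1] - lp[i])
}

#' Power to detect a drug effect by stochastic simulation and estimation
#'
#' For each sample size and replicate, a trial is simulated from the full
#' model (with its drug effect), then both the full model (drug estimated)
#' and the reduced model (drug fixed to zero) are refitted; the drug effect
#' is declared significant when the OFV drop exceeds 3.84 (p = 0.05, 1 df).
#' Power is the fraction of significant replicates, with a 95% binomial
#' confidence interval, and the sample size reaching the target power is
#' read off the (isotonic, logit-scale) interpolated power curve.
#'
#' @param icc `icc_params` used both to simulate and to fit (fixed ICCs).
#' @param p,re Simulation model ([long_params()], [re_spec()]); set
#'   `p$drug = 0` for a type-I error run, or use [type1_error()].
#' @param sizes Sample sizes (subjects per simulated trial).
#' @param n_reps Replicates per sample size.
#' @param seed Master seed; per-replicate seeds are derived
#'   deterministically, so results do not depend on evaluation order.
#' @param design_args Extra arguments for [trial_design()] (e.g.
#'   `model = "ipss"`).
#' @param dofv_crit Significance threshold on the OFV drop.
#' @param target Target power for the interpolated sample size.
#' @param control Optimizer control for the replicate fits.
#' @return A `power_result`: `table` (n, reps, failed, significant, power,
#'   ci_lo, ci_hi), `n_target`, `target`, `failure_rate`.
#' @export
sse_power <- function(icc, p, re, sizes, n_reps, seed,
                      design_args = list(), dofv_crit = 3.84,
                      target = 0.8, control = list()) {
  seeds <- matrix(.derive_seeds(seed, length(sizes) * n_reps),
                  nrow = length(sizes))
  p_sim <- p
  p_nodrug <- p; p_nodrug$drug <- rep(0, p$m)
  rows <- list()
  n_failed_total <- 0
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    sig <- logical(0); failed <- 0
    for (r in seq_len(n_reps)) {
      des <- do.call(trial_design, c(list(n_subjects = n,
                                          covariates = NULL,
                                          screening = FALSE), design_args))
      ds <- simulate_trial(des, icc, p_sim, re, seed = seeds[si, r])
      ctrl <- modifyList(list(rel.tol = 1e-5, iter.max = 150), control)
      res <- tryCatch({
        # two-stage full fit (variance components fixed, then released),
        # then the reduced fit warm-started from the full estimates
        fA <- fit_longitudinal(ds, icc, p_nodrug2full(p_sim), re,
                               include_drug = TRUE, fix_variance = TRUE,
                               control = ctrl)
        full <- fit_longitudinal(ds, icc, fA$params, re,
                                 include_drug = TRUE, control = ctrl)
        pw <- full$params
        pw$drug <- rep(0, p_sim$m)
        red <- fit_longitudinal(ds, icc, pw, full$re,
                                include_drug = FALSE, control = ctrl)
        red$ofv - full$ofv
      }, error = function(e) NA_real_)
      if (is.na(res)) failed <- failed + 1 else sig <- c(sig, res > dofv_crit)
    }
    n_failed_total <- n_failed_total + failed
    ci <- if (length(sig) > 0)
      as.numeric(binom.test(sum(sig), length(sig))$conf.int) else c(NA, NA)
    rows[[si]] <- data.frame(n = n, reps = length(sig), failed = failed,
                             significant = sum(sig),
                             power = mean(sig), ci_lo = ci[1], ci_hi = ci[2])
  }
  tab <- do.call(rbind, rows)
  frate <- n_failed_total / (length(sizes) * n_reps)
  if (frate > 0.05)
    warning(sprintf("replicate fit failure rate %.1f%% exceeds 5%%",
                    100 * frate))
  structure(list(table = tab,
                 n_target = .interp_n(tab$n, tab$power, target),
                 target = target, dofv_crit = dofv_crit,
                 failure_rate = frate),
            class = "power_result")
}

# starting values for the full-model refit: simulation truth (or, for a
# null simulation, a small nonzero drug start so the parameter can move)
p_nodrug2full <- function(p) {
  if (all(p$drug == 0)) p$drug <- rep(-0.1, p$m)
  p
}

#' @export
#' @method print power_result
print.power_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.na(x$n_target))
    cat(sprintf("interpolated n at %.0f%% power: %.1f\n", 100 * x$target,
                x$n_target))
  invisible(x)
}

#' Type-I error of the drug-effect likelihood-ratio test
#'
#' As [sse_power()] but simulating from the model with no drug effect; the
#' reported "power" is the null rejection rate, which should sit near the
#' nominal 0.05 of the 3.84 OFV criterion at every sample size.
#'
#' @inheritParams sse_power
#' @export
type1_error <- function(icc, p, re, sizes, n_reps, seed,
                        design_args = list(), dofv_crit = 3.84,
                        control = list()) {
  p0 <- p; p0$drug <- rep(0, p$m)
  out <- sse_power(icc, p0, re, sizes, n_reps, seed,
                   design_args = design_args, dofv_crit = dofv_crit,
                   target = 0.8, control = control)
  out$n_target <- NA_real_
  out
}

#' Categorical visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the fitted parameter values on
#' the observed design (same subjects, doses, visit schedule, item
#' schedule), and compares the observed proportion of each score category
#' per item and visit against the 2.5/50/97.5 percentiles of the simulated
#' proportions.
#'
#' @param ds Observed `pro_dataset`.
#' @param icc Fixed `icc_params`.
#' @param p,re Fitted longitudinal parameters and BSV specification.
#' @param n_sim Number of replicate simulations.
#' @param seed Master seed.
#' @return A `vpc_result` data frame: `ITEM`, `VISIT`, `TIME`, `category`,
#'   `observed`, `sim_lo`, `sim_med`, `sim_hi`.
#' @export
vpc <- function(ds, icc, p, re, n_sim = 200, seed = 1) {
  m <- p$m
  keep <- intersect(names(icc), unique(ds$ITEM))
  icc <- icc[keep]; class(icc) <- "icc_params"
  ds <- ds[ds$ITEM %in% keep, , drop = FALSE]
  Sigma <- .re_cov(re, m)
  ids <- unique(ds$ID)
  subj <- match(ds$ID, ids)
  dose <- tapply(ds$DOSE, factor(ds$ID, levels = ids), function(x) x[1])
  covs <- list()
  if (!is.null(p$covariates) && nrow(p$covariates) > 0)
    for (cn in unique(p$covariates$covariate))
      covs[[cn]] <- tapply(ds[[cn]], factor(ds$ID, levels = ids),
                           function(x) x[1])
  key_t <- sort(unique(ds$TIME))
  cell_key <- paste(ds$ITEM, ds$VISIT, sep = "@")
  ncat <- setNames(vapply(icc, `[[`, 0L, "ncat"), names(icc))

  prop_table <- function(dv) {
    # proportions per item-visit cell and category
    out <- list()
    for (ck in unique(cell_key)) {
      sel <- cell_key == ck
      it <- sub("@.*", "", ck)
      tabu <- tabulate(dv[sel] + 1L, nbins = ncat[[it]])
      out[[ck]] <- tabu / sum(tabu)
    }
    out
  }
  obs <- prop_table(ds$DV)

  seeds <- .derive_seeds(seed, n_sim)
  sims <- vector("list", n_sim)
  for (s in seq_len(n_sim)) {
    set.seed(seeds[s])
    etas <- MASS::mvrnorm(length(ids), rep(0, m + 3), Sigma)
    if (length(ids) == 1) etas <- matrix(etas, 1)
    psi <- array(0, c(length(ids), length(key_t), m))
    for (i in seq_along(ids)) {
      eta_i <- list(baseline = etas[i, seq_len(m)], pmax = etas[i, m + 1],
                    drift = etas[i, m + 2], log_tprog = etas[i, m + 3])
      psi[i, , ] <- disability(key_t, dose[i], p, eta = eta_i,
                               covariates = lapply(covs, `[`, i))
    }
    dv <- integer(nrow(ds))
    for (it in names(icc)) {
      sel <- ds$ITEM == it
      ti <- match(ds$TIME[sel], key_t)
      pm <- psi[cbind(rep(subj[sel], m), rep(ti, m),
                      rep(seq_len(m), each = sum(sel)))]
      pm <- matrix(pm, ncol = m)
      dv[sel] <- grm_sample_score(icc[[it]], if (m == 1) pm[, 1] else pm)
    }
    sims[[s]] <- prop_table(dv)
  }

  rows <- list()
  for (ck in unique(cell_key)) {
    it <- sub("@.*", "", ck)
    vi <- as.integer(sub(".*@", "", ck))
    tm <- ds$TIME[match(ck, cell_key)]
    simmat <- do.call(rbind, lapply(sims, `[[`, ck))
    qs <- apply(simmat, 2, quantile, probs = c(0.025, 0.5, 0.975))
    for (k in seq_len(ncat[[it]])) {
      rows[[length(rows) + 1]] <- data.frame(
        ITEM = it, VISIT = vi, TIME = tm, category = k - 1L,
        observed = obs[[ck]][k], sim_lo = qs[1, k], sim_med = qs[2, k],
        sim_hi = qs[3, k])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vpc_result", "data.frame")
  out
}
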