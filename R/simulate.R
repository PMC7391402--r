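#' Trial design for simulation
#'
#' Defaults reproduce the reference Phase II design: 403 patients allocated
#' equally to placebo and 10/20/30 mg single-dose arms; assessments at
#' baseline, 14 days (0.47 months) and monthly through 6 months; item-level
#' IPSS and QoL at every visit and the summary BII at baseline, 3 and 6
#' months.  The optional screening rule (total IPSS >= 13 and QoL >= 3 at
#' baseline) is applied by rejection sampling on the simulated baseline
#' responses and is off by default so that simulated data exactly follow the
#' generative model used by the estimation steps.
#'
#' @param n_subjects Total number of subjects.
#' @param doses Dose levels (mg), 0 = placebo.
#' @param allocation Subjects per dose; default near-equal split.
#' @param visit_times Assessment times in months.
#' @param bii_times Times at which the summary BII is assessed.
#' @param model `"integrated"` (IPSS + QoL + BII) or `"ipss"`.
#' @param covariates Named list of covariate simulators; the default
#'   specification draws post-void residual volume (PVR, mL) from a
#'   lognormal with median 50 and geometric SD 2.  Set to `NULL` to simulate
#'   no covariates.
#' @param screening Apply the enrollment screening rule.
#' @return A `trial_design` object.
#' @export
trial_design <- function(n_subjects = 403, doses = c(0, 10, 20, 30),
                         allocation = NULL,
                         visit_times = c(0, 14 / 30, 1, 2, 3, 4, 5, 6),
                         bii_times = c(0, 3, 6),
                         model = c("integrated", "ipss"),
                         covariates = list(PVR = list(dist = "lognormal",
                                                      median = 50, gsd = 2)),
                         screening = FALSE) {
  model <- match.arg(model)
  if (is.null(allocation)) {
    allocation <- rep(n_subjects %/% length(doses), length(doses))
    extra <- n_subjects - sum(allocation)
    if (extra > 0) allocation[seq_len(extra)] <- allocation[seq_len(extra)] + 1
  }
  stopifnot(sum(allocation) == n_subjects, all(diff(visit_times) > 0))
  structure(list(n_subjects = n_subjects, doses = doses,
                 allocation = allocation, visit_times = visit_times,
                 bii_times = bii_times, model = model,
                 covariates = covariates, screening = screening),
            class = "trial_design")
}

# draw covariates for n subjects per the design spec
.sim_covariates <- function(design, n) {
  out <- list()
  for (nm in names(design$covariates)) {
    cv <- design$covariates[[nm]]
    if (cv$dist != "lognormal") stop("unsupported covariate distribution")
    out[[nm]] <- stats::rlnorm(n, meanlog = log(cv$median),
                               sdlog = log(cv$gsd))
  }
  out
}

#' Simulate a clinical trial from the latent IRT model
#'
#' Per subject: random effects are drawn from the between-subject
#' variability specification, the latent disability trajectory follows the
#' longitudinal model, and each scheduled item response is drawn from its
#' graded-response category distribution at the visit's latent value.
#' Fully reproducible given `seed`.
#'
#' @param design A [trial_design()].
#' @param icc An `icc_params` set (its dimension count must match `p`).
#' @param p A [long_params()] object.
#' @param re A [re_spec()] object.
#' @param seed Optional integer seed.
#' @return A `pro_dataset` with one row per simulated item response and any
#'   simulated covariates as columns.
#' @export
#' @examples
#' ref <- reference_params("longitudinal")
#' ds <- simulate_trial(trial_design(n_subjects = 8),
#'                      reference_params("icc"), ref$params, ref$re,
#'                      seed = 1)
#' head(ds)
simulate_trial <- function(design, icc, p, re, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- p$m
  if (attr(icc, "n_dim") != m)
    stop("ICC set and longitudinal parameters have different dimensions")
  specs <- item_specs(design$model)
  icc <- icc[intersect(names(icc), specs$item)]
  class(icc) <- "icc_params"; attr(icc, "n_dim") <- m
  Sigma <- .re_cov(re, m)

  sim_block <- function(doses_vec) {
    n <- length(doses_vec)
    etas <- MASS::mvrnorm(n, mu = rep(0, m + 3), Sigma = Sigma)
    if (n == 1) etas <- matrix(etas, 1)
    covs <- .sim_covariates(design, n)
    tt <- design$visit_times
    nv <- length(tt)
    # psi: n x nv x m
    psi <- array(0, c(n, nv, m))
    for (i in seq_len(n)) {
      eta_i <- list(baseline = etas[i, seq_len(m)], pmax = etas[i, m + 1],
                    drift = etas[i, m + 2], log_tprog = etas[i, m + 3])
      cov_i <- lapply(covs, `[`, i)
      psi[i, , ] <- disability(tt, doses_vec[i], p, eta = eta_i,
                               covariates = cov_i)
    }
    recs <- list()
    for (j in seq_along(icc)) {
      it <- icc[[j]]
      vis <- if (it$scale == "BII") which(tt %in% design$bii_times) else
        seq_len(nv)
      for (v in vis) {
        pm <- psi[, v, , drop = FALSE]; dim(pm) <- c(n, m)
        y <- grm_sample_score(it, if (m == 1) pm[, 1] else pm)
        recs[[length(recs) + 1]] <- data.frame(
          ID = seq_len(n), TIME = tt[v], VISIT = v, DOSE = doses_vec,
          ITEM = it$item, DV = y)
      }
    }
    df <- do.call(rbind, recs)
    for (nm in names(covs)) df[[nm]] <- covs[[nm]][df$ID]
    list(df = df, n = n)
  }

  doses_all <- rep(design$doses, times = design$allocation)
  if (!design$screening) {
    df <- sim_block(doses_all)$df
  } else {
    # rejection sampling on the simulated baseline responses, per arm, so
    # that each accepted subject keeps the dose it was simulated under
    kept <- list(); next_id <- 0
    screen_ok <- function(bdf) {
      base <- bdf[bdf$TIME == 0, ]
      ip <- base$ITEM %in% paste0("IPSS", 1:7)
      ipss0 <- tapply(base$DV[ip], base$ID[ip], sum)
      qol0 <- setNames(base$DV[base$ITEM == "QoL"],
                       base$ID[base$ITEM == "QoL"])
      if (length(qol0) == 0) qol0 <- setNames(rep(6, length(ipss0)),
                                              names(ipss0))
      as.integer(names(ipss0))[ipss0 >= 13 & qol0[names(ipss0)] >= 3]
    }
    for (ai in seq_along(design$doses)) {
      quota <- design$allocation[ai]
      got <- 0; attempts <- 0
      while (got < quota) {
        nb <- quota - got
        bdf <- sim_block(rep(design$doses[ai], nb))$df
        ok <- screen_ok(bdf)
        attempts <- attempts + nb
        if (attempts >= 1000 && (got + length(ok)) / attempts < 0.001)
          stop("screening rule acceptance below 0.1%; infeasible design")
        for (id in ok) {
          if (got >= quota) break
          sub <- bdf[bdf$ID == id, , drop = FALSE]
          next_id <- next_id + 1; got <- got + 1
          sub$ID <- next_id
          kept[[next_id]] <- sub
        }
      }
    }
    df <- do.call(rbind, kept)
  }
  df <- df[order(df$ID, df$VISIT, match(df$ITEM, specs$item)), ]
  rownames(df) <- NULL
  as_pro_dataset(df, specs = specs)
}

#' Simulate item scores at fixed latent values
#'
#' Draws `n_per_psi` independent scores per item at each supplied latent
#' value; empirical frequencies converge to [grm_category_probs()].
#'
#' @param icc An `icc_params` object.
#' @param psi Latent values (unidimensional) defining the strata.
#' @param n_per_psi Draws per stratum.
#' @param seed Optional seed.
#' @return A data frame: `psi`, `ITEM`, `DV`.
#' @export
simulate_scores_at_psi <- function(icc, psi, n_per_psi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_per_psi == 0 || length(psi) == 0)
    return(data.frame(psi = numeric(0), ITEM = character(0), DV = integer(0)))
  out <- list()
  for (ps in psi) {
    for (it in icc) {
      out[[length(out) + 1]] <- data.frame(
        psi = ps, ITEM = it$item,
        DV = grm_sample_score(it, rep(ps, n_per_psi)))
    }
  }
  do.call(rbind, out)
}
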