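#' Empirical Bayes (MAP) estimate of latent disability
#'
#' Maximizes the log prior plus the item response log-likelihoods for one
#' subject-visit.  For the unidimensional graded response model the
#' posterior is unimodal and the mode is found by bounded scalar
#' optimization; for two dimensions a quasi-Newton search is used.
#'
#' @param icc An `icc_params` object.
#' @param scores Named integer vector of observed item scores (names are
#'   item IDs present in `icc`); may be empty.
#' @param prior_mean,prior_var Latent prior for this visit (baseline:
#'   0 and 1; post-baseline: the estimated shift), scalars or length-m.
#' @return The MAP latent value (length m).  With no observations the prior
#'   mean is returned with attribute `no_data = TRUE`.
#' @export
#' @examples
#' icc <- reference_params("icc")
#' estimate_ebe(icc, c(IPSS1 = 3, QoL = 4))
estimate_ebe <- function(icc, scores, prior_mean = 0, prior_var = 1) {
  m <- attr(icc, "n_dim")
  prior_mean <- rep(prior_mean, length.out = m)
  prior_var <- rep(prior_var, length.out = m)
  scores <- scores[names(scores) %in% names(icc)]
  if (length(scores) == 0)
    return(structure(prior_mean, no_data = TRUE))
  items <- icc[names(scores)]
  neglogpost <- function(psi) {
    lp <- sum(dnorm(psi, prior_mean, sqrt(prior_var), log = TRUE))
    ll <- sum(vapply(seq_along(items), function(i) {
      P <- grm_category_probs(items[[i]], if (m == 1) psi else matrix(psi, 1))
      log(max(P[1, scores[i] + 1], 1e-300))
    }, 0))
    -(lp + ll)
  }
  if (m == 1) {
    optimize(neglogpost, c(-12, 12), tol = 1e-6)$minimum
  } else {
    optim(prior_mean, neglogpost, method = "BFGS")$par
  }
}

#' Per subject-visit empirical Bayes estimates for a dataset
#'
#' Computes the MAP latent disability for every subject-visit, using the
#' fixed standard-normal prior at baseline and the post-baseline shift
#' distribution elsewhere.
#'
#' @param icc An `icc_params` object (unidimensional).
#' @param ds A `pro_dataset`.
#' @param post_mean,post_var Post-baseline latent distribution.
#' @return A data frame: `ID`, `VISIT`, `TIME`, `post`, `ebe`.
#' @export
ebe_table <- function(icc, ds, post_mean = -1.53, post_var = 2.59) {
  ds <- ds[ds$ITEM %in% names(icc), , drop = FALSE]
  key <- paste(ds$ID, ds$VISIT, sep = "/")
  idx <- split(seq_len(nrow(ds)), factor(key, levels = unique(key)))
  out <- lapply(idx, function(i) {
    post <- ds$TIME[i[1]] > 0
    sc <- setNames(ds$DV[i], ds$ITEM[i])
    data.frame(ID = ds$ID[i[1]], VISIT = ds$VISIT[i[1]], TIME = ds$TIME[i[1]],
               post = post,
               ebe = estimate_ebe(icc, sc,
                                  prior_mean = if (post) post_mean else 0,
                                  prior_var = if (post) post_var else 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Eta-shrinkage of the empirical Bayes estimates
#'
#' `100 (1 - SD(EBE deviations) / SD(prior))`, computed on the post-baseline
#' subject-visits: when items are informative the EBEs spread almost as the
#' prior and shrinkage is near 0; with no item data every EBE collapses to
#' the prior mean (100%).
#'
#' @inheritParams ebe_table
#' @return Shrinkage in percent.
#' @export
eta_shrinkage <- function(icc, ds, post_mean = -1.53, post_var = 2.59) {
  tab <- ebe_table(icc, ds, post_mean, post_var)
  tab <- tab[tab$post, , drop = FALSE]
  if (nrow(tab) < 2) return(100)
  100 * (1 - sd(tab$ebe - post_mean) / sqrt(post_var))
}

#' Concordance of latent disability with observed scale scores
#'
#' Pairs the per-visit empirical Bayes latent disability with the observed
#' total IPSS, QoL score and summary BII: Pearson correlations across all
#' subject-visits, and a change-from-baseline analysis giving, for each
#' observed score-decrease threshold, the fraction of post-baseline
#' subject-visits whose latent disability decreased from baseline.
#'
#' @inheritParams ebe_table
#' @param max_change Largest score decrease tabulated per scale.
#' @return A list: `correlations` (named vector over IPSS, QoL, BII),
#'   `changes` (data frame: scale, change, n, frac_ebe_decreased), `ebe`
#'   (the per-visit EBE table joined with observed totals).
#' @export
ebe_score_concordance <- function(icc, ds, post_mean = -1.53, post_var = 2.59,
                                  max_change = 6) {
  tab <- ebe_table(icc, ds, post_mean, post_var)
  tot <- .observed_totals(ds)
  tab <- merge(tab, tot[, c("ID", "VISIT", "IPSS", "QoL", "BII")],
               by = c("ID", "VISIT"), all.x = TRUE)
  safe_cor <- function(x, y)
    if (sum(complete.cases(x, y)) > 2) cor(x, y, use = "complete.obs")
    else NA_real_
  cors <- c(IPSS = safe_cor(tab$ebe, tab$IPSS),
            QoL = safe_cor(tab$ebe, tab$QoL),
            BII = safe_cor(tab$ebe, tab$BII))
  base <- tab[!tab$post, c("ID", "ebe", "IPSS", "QoL", "BII")]
  names(base) <- c("ID", "ebe0", "IPSS0", "QoL0", "BII0")
  ch <- merge(tab[tab$post, ], base, by = "ID")
  ch$debe <- ch$ebe - ch$ebe0
  rows <- list()
  for (scale in c("IPSS", "QoL", "BII")) {
    d <- ch[[scale]] - ch[[paste0(scale, "0")]]
    for (k in seq_len(max_change)) {
      sel <- !is.na(d) & d <= -k
      if (sum(sel) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        scale = scale, change = -k, n = sum(sel),
        frac_ebe_decreased = 100 * mean(ch$debe[sel] < 0))
    }
  }
  list(correlations = cors, changes = do.call(rbind, rows), ebe = tab)
}
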