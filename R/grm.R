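#' Graded-response cumulative probability
#'
#' Probability of answering at least `k`:
#' `P(Y >= k) = exp(a (psi - b)) / (1 + exp(a (psi - b)))`, evaluated
#' overflow-safely.  Strictly increasing in `psi` for `a > 0`.
#'
#' @param a Discrimination (slope) parameter.
#' @param b Difficulty (location) threshold for the category boundary.
#' @param psi Latent disability value(s).
#' @return Probabilities, vectorized over any argument.
#' @export
#' @examples
#' grm_cum_prob(1.22, 0, 0) # 0.5 at the item's center
grm_cum_prob <- function(a, b, psi) {
  plogis(a * (psi - b))
}

#' Compensatory cumulative probability
#'
#' Multidimensional extension where several latent variables jointly drive
#' the response: `P(Y >= k) = logistic(sum_d a_d psi_d - B_k)`.  With a
#' single nonzero loading this reduces exactly to [grm_cum_prob()] with
#' `b = B / a`.
#'
#' @param a Vector of discriminations, one per latent dimension.
#' @param B Overall difficulty intercept for the category boundary.
#' @param psi Vector of latent values, same length as `a`.
#' @return A probability.
#' @export
grm_compensatory_cum_prob <- function(a, B, psi) {
  if (length(a) != length(psi)) stop("dimension mismatch between a and psi")
  plogis(sum(a * psi) - B)
}

# linear predictor sum_d a_d * psi_d for one item; psi: vector (one latent
# state) or matrix (rows = states, cols = dimensions)
.item_linpred <- function(item, psi) {
  if (is.matrix(psi)) {
    if (max(item$dims) > ncol(psi)) stop("dimension mismatch for item ", item$item)
    drop(psi[, item$dims, drop = FALSE] %*% item$a)
  } else {
    if (length(item$dims) == 1) {
      if (length(psi) > 1 && max(item$dims) == 1) item$a * psi
      else item$a * psi[item$dims]
    } else {
      if (max(item$dims) > length(psi)) stop("dimension mismatch for item ", item$item)
      sum(item$a * psi[item$dims])
    }
  }
}

#' Category probabilities for an item
#'
#' Maps cumulative probabilities to category probabilities:
#' `P(0) = 1 - P(>=1)`, `P(k) = P(>=k) - P(>=k+1)`, `P(X) = P(>=X)`.
#' The result is a proper distribution over scores `0..X` for every latent
#' value.
#'
#' @param item One element of an [icc_params()] object.
#' @param psi Latent value(s): a numeric vector (unidimensional items,
#'   vectorized) or a matrix with one row per latent state and one column
#'   per dimension.
#' @return A matrix with one row per latent state and columns `0..X`.
#' @export
grm_category_probs <- function(item, psi) {
  lin <- .item_linpred(item, psi)
  Q <- plogis(outer(lin, item$B, `-`)) # n x X cumulative P(Y >= k)
  P <- cbind(1 - Q[, 1, drop = FALSE],
             if (ncol(Q) > 1) Q[, -ncol(Q), drop = FALSE] - Q[, -1, drop = FALSE],
             Q[, ncol(Q), drop = FALSE])
  colnames(P) <- 0:(item$ncat - 1)
  P
}

#' Draw item scores at given latent values
#'
#' Inverse-CDF draws from [grm_category_probs()]; reproducible under
#' `set.seed`.
#'
#' @inheritParams grm_category_probs
#' @return Integer scores, one per latent state.
#' @export
grm_sample_score <- function(item, psi) {
  P <- grm_category_probs(item, psi)
  cum <- t(apply(P, 1, cumsum))
  u <- runif(nrow(P))
  as.integer(rowSums(cum < u))
}

#' Fisher information of an item
#'
#' Item information `I_j(psi)`, minus the expectation (over the category
#' distribution at `psi`) of the second derivative of the log-likelihood.
#' For the graded response model this has the closed form
#' `sum_k (P_k')^2 / P_k` with `P_k' = dP_k/dpsi` assembled from logistic
#' derivatives `a Q_k (1 - Q_k)`.
#'
#' @param item A unidimensional item from [icc_params()].
#' @param psi Latent values (vectorized).
#' @return Non-negative information values.
#' @export
item_information <- function(item, psi) {
  if (length(item$dims) != 1)
    stop("information is defined for unidimensional items only")
  Q <- plogis(item$a * outer(psi, item$b, `-`))
  dQ <- item$a * Q * (1 - Q)
  X <- ncol(Q)
  P <- cbind(1 - Q[, 1], if (X > 1) Q[, -X, drop = FALSE] - Q[, -1, drop = FALSE],
             Q[, X])
  dP <- cbind(-dQ[, 1], if (X > 1) dQ[, -X, drop = FALSE] - dQ[, -1, drop = FALSE],
              dQ[, X])
  rowSums(dP^2 / pmax(P, 1e-300))
}

#' Quantiles of the study latent-disability mixture
#'
#' The latent disability observed over a trial is a mixture of the baseline
#' standard-normal distribution and the post-baseline shifted distribution,
#' weighted by the fraction of assessment visits in each state (1/8 baseline,
#' 7/8 post-baseline for the reference design).
#'
#' @param p Probabilities.
#' @param post_mean,post_var Post-baseline latent distribution.
#' @param w_baseline Mixture weight of the baseline component.
#' @return Quantiles, found numerically.
#' @export
latent_mixture_quantile <- function(p, post_mean = -1.53, post_var = 2.59,
                                    w_baseline = 1 / 8) {
  cdf <- function(x) w_baseline * pnorm(x) +
    (1 - w_baseline) * pnorm(x, post_mean, sqrt(post_var))
  vapply(p, function(pp)
    uniroot(function(x) cdf(x) - pp, c(-40, 40), tol = 1e-10)$root, 0)
}

#' Rank items by Fisher-information content
#'
#' Evaluates each item's information function on a grid spanning the study
#' population's latent-disability range, integrates by the trapezoid rule,
#' and expresses each item's area as a percentage of the summed areas.  The
#' default range covers the central 99.8% (0.1--99.9 percentile span) of the
#' baseline/post-baseline latent mixture, i.e. essentially the whole study
#' population; `level = 0.95` restricts to the central 95% band.
#'
#' @param icc An [icc_params()] object (unidimensional).
#' @param post_mean,post_var,w_baseline Latent mixture; see
#'   [latent_mixture_quantile()].
#' @param level Central mixture mass spanned by the integration grid.
#' @param grid_n Number of equally spaced grid points.
#' @return An `info_profile` object: a data frame (item, subscale, auc,
#'   fraction, cum_fraction) sorted by decreasing information share, with the
#'   evaluation grid and per-item information values as attributes.
#' @export
#' @examples
#' ip <- information_ranking(reference_params("icc"))
#' ip
information_ranking <- function(icc, post_mean = -1.53, post_var = 2.59,
                                w_baseline = 1 / 8, level = 0.998,
                                grid_n = 201) {
  if (length(icc) == 0) stop("empty item set")
  if (attr(icc, "n_dim") > 1)
    stop("information ranking is defined for the unidimensional model only")
  qq <- latent_mixture_quantile(c((1 - level) / 2, 1 - (1 - level) / 2),
                                post_mean, post_var, w_baseline)
  grid <- seq(qq[1], qq[2], length.out = grid_n)
  h <- diff(grid)
  infomat <- vapply(icc, function(it) item_information(it, grid),
                    numeric(grid_n))
  auc <- apply(infomat, 2, function(y) sum(h * (head(y, -1) + tail(y, -1)) / 2))
  fraction <- 100 * auc / sum(auc)
  out <- data.frame(item = names(icc),
                    subscale = vapply(icc, `[[`, "", "subscale"),
                    auc = auc, fraction = fraction,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$fraction), ]
  out$cum_fraction <- cumsum(out$fraction)
  rownames(out) <- NULL
  structure(out, class = c("info_profile", "data.frame"),
            grid = grid, information = infomat, range = qq)
}

#' @export
#' @method print info_profile
print.info_profile <- function(x, ...) {
  rng <- attr(x, "range")
  cat(sprintf("Fisher information ranking over disability range [%.2f, %.2f]\n",
              rng[1], rng[2]))
  df <- data.frame(item = x$item, subscale = x$subscale,
                   `pct of total` = round(x$fraction, 1),
                   `cumulative pct` = round(x$cum_fraction, 1),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export an information profile as CSV
#'
#' @param x An `info_profile` from [information_ranking()].
#' @param path Output CSV path.
#' @export
write_info_profile <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
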