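# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written from first principles (dense-grid
# integration, finite differences) and never call the code paths they check.

ref_icc <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- reference_params("icc")
    val
  }
})

ref_long <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- reference_params("longitudinal")
    val
  }
})

# a small two-item instrument (one binary, one 4-category item)
tiny_icc <- function() {
  sp <- data.frame(item = c("A", "B"), ncat = c(2L, 4L),
                   scale = c("IPSS", "IPSS"),
                   subscale = c("voiding", "storage"),
                   label = c("A", "B"))
  icc_params(list(A = list(a = 0.9, b = -0.4),
                  B = list(a = 1.3, b = c(-1.2, 0.3, 1.1))), specs = sp)
}

# category probabilities computed from first principles (independent of
# grm_category_probs): cumulative logistic differences
oracle_cat_probs <- function(a, b, psi) {
  Q <- 1 / (1 + exp(-a * (psi - b)))
  c(1 - Q[1], if (length(b) > 1) Q[-length(b)] - Q[-1], Q[length(b)])
}

# dense-trapezoid marginal -2 log likelihood of the pooled ICC model
brute_icc_ofv <- function(ds, icc, post_mean, post_var, ngrid = 1000,
                          lim = c(-12, 12)) {
  g <- seq(lim[1], lim[2], length.out = ngrid)
  h <- g[2] - g[1]
  total <- 0
  for (key in unique(paste(ds$ID, ds$VISIT))) {
    rows <- ds[paste(ds$ID, ds$VISIT) == key, ]
    post <- rows$TIME[1] > 0
    dens <- if (post) dnorm(g, post_mean, sqrt(post_var)) else dnorm(g)
    lik <- dens
    for (r in seq_len(nrow(rows))) {
      it <- icc[[rows$ITEM[r]]]
      lik <- lik * vapply(g, function(psi)
        oracle_cat_probs(it$a, it$b, psi)[rows$DV[r] + 1], 0)
    }
    total <- total + log(h * (sum(lik) - (lik[1] + lik[ngrid]) / 2))
  }
  -2 * total
}

# dense-grid 4-D integral of the longitudinal marginal likelihood
# (etas: baseline, pmax, drift, log tprog), for very small instances
brute_long_ofv <- function(ds, icc, p, re, ngrid = 15, width = 4) {
  S <- proirt:::.re_cov(re, 1)
  Sinv <- solve(S)
  dets <- determinant(S)$modulus
  axes <- lapply(sqrt(diag(S)), function(s)
    seq(-width * s, width * s, length.out = ngrid))
  hs <- vapply(axes, function(a) a[2] - a[1], 0)
  grid <- as.matrix(expand.grid(axes))
  ldens <- -0.5 * rowSums((grid %*% Sinv) * grid) -
    0.5 * (4 * log(2 * pi) + as.numeric(dets))
  total <- 0
  for (id in unique(ds$ID)) {
    rows <- ds[ds$ID == id, ]
    ll <- ldens
    for (r in seq_len(nrow(rows))) {
      t <- rows$TIME[r]
      it <- icc[[rows$ITEM[r]]]
      lam <- log(2) / (p$tprog * exp(grid[, 4]))
      pl <- if (t > 0)
        (p$pmax + grid[, 2]) * (1 - exp(-(lam * t)^p$wei)) +
          (p$drift + grid[, 3]) * t else 0
      drug <- if (t > 0 && rows$DOSE[r] > 0) p$drug else 0
      psi <- p$baseline + grid[, 1] + pl + drug
      Q <- plogis(it$a * outer(psi, it$b, `-`))
      X <- length(it$b)
      P <- cbind(1 - Q[, 1],
                 if (X > 1) Q[, -X, drop = FALSE] - Q[, -1, drop = FALSE],
                 Q[, X])
      ll <- ll + log(pmax(P[, rows$DV[r] + 1], 1e-300))
    }
    total <- total + log(sum(exp(ll - max(ll)))) + max(ll) + sum(log(hs))
  }
  -2 * total
}

# item information by central-difference differentiation of the category
# log-probabilities: -E[ d2/dpsi2 log P(Y = k | psi) ]
numeric_item_info <- function(item, psi, h = 1e-4) {
  vapply(psi, function(p0) {
    P0 <- grm_category_probs(item, p0)[1, ]
    d2 <- vapply(seq_along(P0), function(k) {
      f <- function(p) log(grm_category_probs(item, p)[1, k])
      (f(p0 + h) - 2 * f(p0) + f(p0 - h)) / h^2
    }, 0)
    -sum(P0 * d2)
  }, 0)
}

# synthetic bidimensional ICC set derived from the unidimensional reference:
# voiding items keep their curves on dimension 1, storage + QoL on
# dimension 2, and the summary BII becomes compensatory with equal loadings
# scaled to preserve its overall discrimination
ref_icc2 <- local({
  val <- NULL
  function() {
    if (!is.null(val)) return(val)
    uni <- reference_params("icc")
    dims <- item_dimensions(item_specs(), "bidimensional")
    items <- lapply(names(uni), function(nm) {
      it <- uni[[nm]]
      if (nm == "BII") {
        a2 <- rep(it$a / sqrt(2), 2)
        list(a = a2, B = it$a * it$b, dims = c(1L, 2L))
      } else list(a = it$a, b = it$b, dims = dims[[nm]])
    })
    names(items) <- names(uni)
    val <<- icc_params(items)
    val
  }
})

# a small simulated trial shared by several tests
small_trial <- local({
  cache <- new.env()
  function(n = 60, seed = 5, model = "integrated") {
    key <- paste(n, seed, model)
    if (is.null(cache[[key]])) {
      ref <- ref_long()
      p <- ref$params
      p$covariates <- NULL
      cache[[key]] <- simulate_trial(
        trial_design(n_subjects = n, model = model, covariates = NULL),
        ref_icc(), p, ref$re, seed = seed)
    }
    cache[[key]]
  }
})
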