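# builds a tiny handcrafted dataset on the two-item instrument
tiny_dataset <- function(n_subj = 5, seed = 11) {
  icc <- tiny_icc()
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subj)) {
    for (v in 1:2) {
      psi <- rnorm(1, if (v == 1) 0 else -1, if (v == 1) 1 else 1.4)
      for (it in icc) {
        rows[[length(rows) + 1]] <- data.frame(
          ID = i, TIME = (v - 1) * 1.0, VISIT = v, DOSE = 0,
          ITEM = it$item, DV = grm_sample_score(it, psi))
      }
    }
  }
  sp <- data.frame(item = c("A", "B"), ncat = c(2L, 4L),
                   scale = "IPSS", subscale = c("voiding", "storage"),
                   label = c("A", "B"))
  list(ds = as_pro_dataset(do.call(rbind, rows), specs = sp), specs = sp)
}

test_that("quadrature marginal OFV matches dense brute-force integration", {
  td <- tiny_dataset()
  icc <- tiny_icc()
  for (shift in list(c(-1, 1.8), c(0.4, 0.6))) {
    ofv_q9 <- proirt:::.icc_ofv(td$ds, icc, shift[1], shift[2], nodes = 9L)
    ofv_q15 <- proirt:::.icc_ofv(td$ds, icc, shift[1], shift[2], nodes = 15L)
    ofv_bf <- brute_icc_ofv(td$ds, icc, shift[1], shift[2], ngrid = 1000)
    expect_equal(ofv_q9, ofv_bf, tolerance = 1e-4)
    expect_equal(ofv_q15, ofv_bf, tolerance = 1e-4)
  }
})

test_that("a null post-baseline shift is recovered as no shift", {
  # independent N(0,1) latents at every visit: post-baseline responses are
  # identical in distribution to baseline, so the shift should vanish
  icc <- ref_icc()[item_specs("ipss")$item]
  set.seed(9)
  rows <- list()
  for (i in 1:150) for (v in 1:8) {
    psi <- rnorm(1)
    for (it in icc)
      rows[[length(rows) + 1]] <- data.frame(
        ID = i, TIME = c(0, 0.47, 1:6)[v], VISIT = v, DOSE = 0,
        ITEM = it$item, DV = grm_sample_score(it, psi))
  }
  ds <- as_pro_dataset(do.call(rbind, rows))
  fit <- fit_icc(ds)
  expect_lt(abs(fit$post_mean), 0.1)
  expect_lt(abs(fit$post_var - 1), 0.15)
})

test_that("custom dimension structures reduce and relabel consistently", {
  td <- tiny_dataset(n_subj = 40, seed = 13)
  icc1 <- tiny_icc()
  # all items on dimension 1 under a 2-D integration grid: identical OFV
  icc2 <- icc1
  attr(icc2, "n_dim") <- 2L
  ofv1 <- proirt:::.icc_ofv(td$ds, icc1, -1, 1.8, nodes = 15L)
  ofv2 <- proirt:::.icc_ofv(td$ds, icc2, -1, 1.8, nodes = 15L)
  expect_equal(ofv1, ofv2, tolerance = 1e-6)

  # swapping dimension labels leaves the fitted OFV unchanged
  f12 <- fit_icc(td$ds, structure = list(A = 1L, B = 2L), specs = td$specs)
  f21 <- fit_icc(td$ds, structure = list(A = 2L, B = 1L), specs = td$specs)
  expect_equal(f12$ofv, f21$ofv, tolerance = 1e-3)
})

test_that("pooled ICC fitting recovers simulated parameters at modest scale", {
  ref <- ref_long()
  p <- ref$params; p$covariates <- NULL
  ds <- simulate_trial(trial_design(n_subjects = 200, model = "ipss",
                                    covariates = NULL),
                       ref_icc(), p, ref$re, seed = 17)
  fit <- fit_icc(ds)
  expect_equal(fit$convergence, 0)
  truth <- ref_icc()
  for (nm in names(fit$icc)) {
    expect_lt(abs(fit$icc[[nm]]$a / truth[[nm]]$a - 1), 0.25, label = nm)
  }
  # the OFV at the estimate beats the OFV at the generating values
  ofv_truth <- proirt:::.icc_ofv(ds, truth[item_specs("ipss")$item],
                                 -1.53, 2.59)
  expect_lt(fit$ofv, ofv_truth + 1e-6)
})

test_that("single-category items are excluded with a warning", {
  td <- tiny_dataset(n_subj = 6, seed = 3)
  ds <- td$ds
  ds$DV[ds$ITEM == "A"] <- 1L # degenerate item
  expect_warning(fit <- fit_icc(ds, specs = td$specs), "single observed")
  expect_false("A" %in% names(fit$icc))
})

test_that("empirical Bayes estimates maximize the posterior", {
  icc <- ref_icc()
  # no data: prior mean, flagged
  e0 <- estimate_ebe(icc, c())
  expect_equal(as.numeric(e0), 0)
  expect_true(attr(e0, "no_data"))
  # all items at maximum score, weak prior: the MAP lies above every
  # threshold's logistic center
  mx <- setNames(item_specs()$ncat - 1L, item_specs()$item)
  etop <- estimate_ebe(icc, mx, prior_mean = 0, prior_var = 25)
  expect_gt(etop, max(vapply(icc, function(it) max(it$b), 0)))
  # bounded optimizer agrees with a dense grid-search oracle
  set.seed(23)
  grid <- seq(-8, 8, by = 1e-4)
  for (k in 1:20) {
    items <- sample(names(icc), sample(3:9, 1))
    sc <- vapply(items, function(nm)
      sample.int(icc[[nm]]$ncat, 1) - 1L, 0L)
    pm <- rnorm(1, -1, 1); pv <- runif(1, 0.5, 3)
    lp <- dnorm(grid, pm, sqrt(pv), log = TRUE)
    for (nm in items)
      lp <- lp + log(grm_category_probs(icc[[nm]], grid)[, sc[[nm]] + 1])
    oracle <- grid[which.max(lp)]
    est <- estimate_ebe(icc, sc, prior_mean = pm, prior_var = pv)
    expect_equal(est, oracle, tolerance = 1e-3)
  }
})

test_that("eta-shrinkage reflects item informativeness", {
  ds <- small_trial(n = 60, seed = 5)
  # nine informative items: little shrinkage
  expect_lt(eta_shrinkage(ref_icc(), ds), 15)
  # uninformative items: EBEs collapse to the prior mean, shrinkage -> 100%
  flat <- icc_params(lapply(setNames(nm = names(ref_icc())), function(nm)
    list(a = 1e-6, b = ref_icc()[[nm]]$b)))
  expect_gt(eta_shrinkage(flat, ds), 99)
})

test_that("compensatory discriminations are recoverable from bidim data", {
  # generator matched to the pooled-ICC model: independent latent vectors
  # per subject-visit, baseline N(0, I), post-baseline shifted
  icc2 <- ref_icc2()
  set.seed(211)
  n_sv <- 1200
  post <- rep(c(0L, 1L), c(300, 900))
  psi <- cbind(rnorm(n_sv, ifelse(post == 1, -1.0, 0),
                     ifelse(post == 1, 1.3, 1)),
               rnorm(n_sv, ifelse(post == 1, -1.2, 0),
                     ifelse(post == 1, 1.5, 1)))
  rows <- list()
  for (it in icc2) {
    rows[[length(rows) + 1]] <- data.frame(
      ID = seq_len(n_sv), TIME = as.numeric(post), VISIT = post + 1L,
      DOSE = 0, ITEM = it$item, DV = grm_sample_score(it, psi))
  }
  ds <- as_pro_dataset(do.call(rbind, rows))
  fit <- fit_icc_multidim(ds)
  a_hat <- fit$icc$BII$a
  a_true <- icc2$BII$a
  expect_length(a_hat, 2)
  expect_true(all(abs(a_hat / a_true - 1) < 0.25))
})

test_that("varimax rotation preserves communalities", {
  ds <- small_trial(n = 80, seed = 19)
  f_rot <- factor_analyze(ds, n_factors = 2)
  f_raw <- factor_analyze(ds, n_factors = 2, rotation = "none")
  expect_equal(f_rot$communalities, f_raw$communalities, tolerance = 1e-8)
  expect_true(all(abs(f_rot$loadings) <= 1))
})

test_that("factor analysis supports one factor for unidimensional data", {
  ds <- small_trial(n = 80, seed = 19)
  f1 <- factor_analyze(ds, n_factors = 1)
  expect_true(all(abs(f1$loadings) > 0.4))
  expect_true(all(f1$assignment == 1))
  expect_false(any(f1$cross_loading))
})
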