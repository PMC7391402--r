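test_that("cumulative probability is the logistic of a(psi - b)", {
  expect_equal(grm_cum_prob(1.22, 0.7, 0.7), 0.5)
  # direct evaluation 1/(1 + exp(-1.19 * 4.56))
  expect_equal(grm_cum_prob(1.19, -4.56, 0), 0.995624, tolerance = 1e-5)
  # flat item: a -> 0 gives 0.5 everywhere
  expect_equal(grm_cum_prob(0, 3, c(-5, 0, 5)), rep(0.5, 3))
  # no overflow deep in the tails
  expect_equal(grm_cum_prob(2, -400, 0), 1)
  expect_equal(grm_cum_prob(2, 400, 0), 0)
  # strictly increasing in psi for a > 0
  expect_true(all(diff(grm_cum_prob(0.9, 0.2, seq(-8, 8, 0.5))) > 0))
})

test_that("category probabilities form a proper distribution everywhere", {
  icc <- ref_icc()
  psi <- seq(-10, 10, length.out = 81)
  for (it in icc) {
    P <- grm_category_probs(it, psi)
    expect_equal(unname(rowSums(P)), rep(1, length(psi)), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    # P(Y >= k) non-increasing in k, non-decreasing in psi
    Q <- plogis(it$a * outer(psi, it$b, `-`))
    expect_true(all(diff(t(Q)) <= 0))
    expect_true(all(diff(Q) >= 0))
  }
  # limit: very low disability concentrates all mass on score 0
  expect_equal(unname(grm_category_probs(icc$IPSS1, -50)[1, ]),
               c(1, rep(0, 5)))
})

test_that("category probabilities match a first-principles composition", {
  it <- ref_icc()$IPSS1
  for (psi in c(-2, 0, 1.5)) {
    expect_equal(unname(grm_category_probs(it, psi)[1, ]),
                 oracle_cat_probs(it$a, it$b, psi), tolerance = 1e-12)
  }
})

test_that("compensatory model reduces to and extends the unidimensional one", {
  sp <- data.frame(item = "C", ncat = 3L, scale = "BII", subscale = "none",
                   label = "C")
  # one active dimension: identical to the unidimensional curve
  expect_identical(grm_compensatory_cum_prob(c(0.8, 0), 0, c(1.0, 99.0)),
                   grm_cum_prob(0.8, 0, 1.0))
  # compensation symmetry: opposite latent values cancel
  expect_equal(grm_compensatory_cum_prob(c(0.5, 0.5), 0, c(2, -2)), 0.5)
  # hand evaluation: logistic(0.3 + 0.7 - 0.5)
  expect_equal(grm_compensatory_cum_prob(c(0.3, 0.7), 0.5, c(1, 1)),
               plogis(0.5), tolerance = 1e-12)
  expect_error(grm_compensatory_cum_prob(c(0.3, 0.7), 0, 1), "dimension")

  # a two-dimensional item with a zero loading is bit-identical to the
  # unidimensional item across the category distribution
  icc2 <- icc_params(list(C = list(a = c(1.1, 2), B = c(-1, 0.8),
                                   dims = c(1, 2))), specs = sp)
  icc1 <- icc_params(list(C = list(a = 1.1, b = c(-1, 0.8) / 1.1)),
                     specs = sp)
  psi2 <- cbind(seq(-4, 4, 0.5), 0)
  P2 <- grm_category_probs(icc2$C, psi2)
  P1 <- grm_category_probs(icc1$C, psi2[, 1])
  expect_identical(P2, P1)
})

test_that("score sampling follows the category distribution", {
  icc <- ref_icc()
  set.seed(42)
  expect_equal(grm_sample_score(icc$QoL, rep(-100, 50)), rep(0L, 50))
  # fixed seed reproduces the sequence
  set.seed(7); s1 <- grm_sample_score(icc$IPSS7, rep(0, 100))
  set.seed(7); s2 <- grm_sample_score(icc$IPSS7, rep(0, 100))
  expect_identical(s1, s2)
  # Monte-Carlo frequencies within 3 SE of the model probabilities
  set.seed(1)
  n <- 1e5
  draws <- grm_sample_score(icc$IPSS7, rep(0, n))
  p <- grm_category_probs(icc$IPSS7, 0)[1, ]
  emp <- tabulate(draws + 1L, nbins = 6) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(emp - p) <= 3 * se))
})

test_that("item information matches its numerical-differentiation oracle", {
  icc <- ref_icc()
  psi <- seq(-6, 3, length.out = 50)
  for (it in icc) {
    expect_equal(item_information(it, psi), numeric_item_info(it, psi),
                 tolerance = 1e-6, label = it$item)
  }
  # two-category item: information is the binary-logistic a^2 p (1 - p)
  sp <- data.frame(item = "D", ncat = 2L, scale = "IPSS",
                   subscale = "voiding", label = "D")
  bin <- icc_params(list(D = list(a = 1.4, b = 0.3)), specs = sp)$D
  p <- plogis(1.4 * (psi - 0.3))
  expect_equal(item_information(bin, psi), 1.4^2 * p * (1 - p),
               tolerance = 1e-12)
  # a -> 0: no information
  flat <- icc_params(list(D = list(a = 1e-8, b = 0.3)), specs = sp)$D
  expect_lt(max(item_information(flat, psi)), 1e-15)
})

test_that("information ranking normalizes, orders and degenerates correctly", {
  icc <- ref_icc()
  prof <- information_ranking(icc)
  expect_equal(sum(prof$fraction), 100, tolerance = 1e-9)
  expect_true(all(attr(prof, "information") >= 0))
  expect_equal(prof$cum_fraction[nrow(prof)], 100, tolerance = 1e-9)
  # the 95%-band option spans a narrower latent range
  prof95 <- information_ranking(icc, level = 0.95)
  expect_equal(sum(prof95$fraction), 100, tolerance = 1e-9)
  expect_lt(diff(attr(prof95, "range")), diff(attr(prof, "range")))

  one <- icc[1]; class(one) <- "icc_params"; attr(one, "n_dim") <- 1L
  expect_equal(information_ranking(one)$fraction, 100)
  twin <- icc_params(list(IPSS1 = list(a = 1.19, b = icc$IPSS1$b),
                          IPSS3 = list(a = 1.19, b = icc$IPSS1$b)))
  expect_equal(information_ranking(twin)$fraction, c(50, 50))
  empty <- structure(list(), class = "icc_params", n_dim = 1L)
  expect_error(information_ranking(empty), "empty")
})

test_that("latent mixture quantiles invert the mixture CDF", {
  q <- latent_mixture_quantile(c(0.025, 0.5, 0.975))
  w <- 1 / 8
  cdf <- function(x) w * pnorm(x) + (1 - w) * pnorm(x, -1.53, sqrt(2.59))
  expect_equal(vapply(q, cdf, 0), c(0.025, 0.5, 0.975), tolerance = 1e-8)
  expect_true(all(diff(q) > 0))
})
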