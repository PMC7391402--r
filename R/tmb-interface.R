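# Internal glue between the R-side model objects and the TMB objective.

# Gauss-Hermite rule for integrals against N(0,1), by Golub-Welsch
# (eigendecomposition of the Jacobi matrix of the Hermite polynomials).
.gh_rule <- function(n) {
  if (n == 1) return(list(z = 0, w = 1))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = sqrt(2) * e$values[ord], w = (e$vectors[1, ]^2)[ord])
}

# m-dimensional product rule on the standard-normal scale
.gh_grid <- function(n, m) {
  r <- .gh_rule(n)
  if (m == 1) return(list(z = matrix(r$z, ncol = 1), logw = log(r$w)))
  g <- expand.grid(seq_len(n), seq_len(n))
  list(z = cbind(r$z[g[, 1]], r$z[g[, 2]]),
       logw = log(r$w[g[, 1]]) + log(r$w[g[, 2]]))
}

# item-structure arrays shared by both TMB models (0-based indices)
.item_arrays <- function(icc) {
  list(ncat = vapply(icc, `[[`, 0L, "ncat"),
       load_n = vapply(icc, function(it) length(it$dims), 0L),
       load_dim = unlist(lapply(icc, function(it) it$dims)) - 1L)
}

# item parameters in TMB layout
.item_pars <- function(icc) {
  list(log_a = log(unlist(lapply(icc, `[[`, "a"))),
       B1 = vapply(icc, function(it) it$B[1], 0),
       log_dB = unlist(lapply(icc, function(it)
         if (it$ncat > 2) log(pmax(diff(it$B), 1e-6)) else numeric(0))))
}

# rebuild an icc_params object from a TMB parameter list
.pars_to_icc <- function(pl, template, specs) {
  items <- list()
  aoff <- 0; boff <- 0
  for (j in seq_along(template)) {
    it <- template[[j]]
    nl <- length(it$dims); X <- it$ncat - 1L
    a <- exp(pl$log_a[aoff + seq_len(nl)])
    dB <- if (X > 1) exp(pl$log_dB[boff + seq_len(X - 1)]) else numeric(0)
    B <- cumsum(c(pl$B1[j], dB))
    items[[it$item]] <- if (nl == 1) list(a = a, b = B / a, dims = it$dims)
      else list(a = a, B = B, dims = it$dims)
    aoff <- aoff + nl; boff <- boff + (X - 1)
  }
  icc_params(items, specs = specs)
}

# map factor helper: all-NA factor of the same length
.map_off <- function(x) factor(rep(NA, length(x)))

#' Fit item characteristic curves by pooled marginal maximum likelihood
#'
#' Stage 1 of the pipeline: data from all individuals and all visits are
#' pooled and every subject-visit receives an independent latent disability
#' drawn from the visit-appropriate distribution -- fixed standard normal at
#' baseline, `N(post_mean, post_var)` post-baseline with both shift
#' parameters estimated.  The marginal likelihood is integrated by
#' Gauss--Hermite quadrature on the prior scale and maximized with exact
#' (automatic-differentiation) gradients.  Threshold ordering is enforced by
#' a first-threshold-plus-log-increments parameterization.
#'
#' @param ds A `pro_dataset`.
#' @param structure `"unidimensional"` or `"bidimensional"` (the latter uses
#'   a compensatory graded response model for the summary BII, which loads
#'   on both dimensions with shared intercepts), or a named list mapping
#'   each item to the integer latent dimension(s) it loads on.
#' @param specs Item specifications.
#' @param nodes Quadrature nodes per dimension (15 for one dimension, 7 per
#'   axis for two).
#' @param start Optional `icc_params` starting values; by default initials
#'   come from logit-transformed empirical cumulative score frequencies.
#' @param se Compute standard errors from the inverse Hessian of the
#'   marginal log-likelihood (slower).
#' @param control Passed to [stats::nlminb()].
#' @return An `icc_fit` object: `icc` (estimates), `post_mean`, `post_var`,
#'   `ofv` (-2 log marginal likelihood), `convergence`, `se` (optional data
#'   frame with RSE%), `excluded_items`.
#' @export
fit_icc <- function(ds, structure = c("unidimensional", "bidimensional"),
                    specs = item_specs(), nodes = NULL, start = NULL,
                    se = FALSE, control = list()) {
  custom_dims <- NULL
  if (is.list(structure)) { # named list: explicit dimension loadings
    custom_dims <- lapply(structure, as.integer)
    m <- max(unlist(custom_dims))
    structure <- "custom"
  } else {
    structure <- match.arg(structure)
    m <- if (structure == "unidimensional") 1L else 2L
  }
  if (m > 2) stop("more than two latent dimensions are unsupported")
  if (is.null(nodes)) nodes <- if (m == 1) 15L else 7L

  present <- intersect(specs$item, unique(ds$ITEM))
  ncats_obs <- vapply(present, function(it)
    length(unique(ds$DV[ds$ITEM == it])), 0L)
  excluded <- present[ncats_obs < 2]
  if (length(excluded) > 0)
    warning("item(s) with a single observed category excluded: ",
            paste(excluded, collapse = ", "))
  present <- setdiff(present, excluded)
  if (length(present) == 0) stop("no estimable items in dataset")
  sp <- specs[match(present, specs$item), , drop = FALSE]
  dims <- if (!is.null(custom_dims)) {
    if (!all(present %in% names(custom_dims)))
      stop("custom structure must name every estimable item")
    custom_dims[present]
  } else item_dimensions(sp, structure)

  ds <- ds[ds$ITEM %in% present, , drop = FALSE]
  sv <- factor(paste(ds$ID, ds$VISIT, sep = "/"),
               levels = unique(paste(ds$ID, ds$VISIT, sep = "/")))
  sv_post <- as.integer(tapply(ds$TIME > 0, sv, any)[levels(sv)])

  # heuristic template from pooled cumulative frequencies
  template <- if (is.null(start)) {
    items <- lapply(seq_len(nrow(sp)), function(i) {
      y <- ds$DV[ds$ITEM == sp$item[i]]
      X <- sp$ncat[i] - 1L
      pg <- vapply(seq_len(X), function(k) (sum(y >= k) + 0.5) / (length(y) + 1), 0)
      B <- -qlogis(pg)
      B <- cummax(B + seq_len(X) * 1e-3) # strictly increasing
      d <- dims[[sp$item[i]]]
      if (length(d) == 1) list(a = 1, b = B, dims = d)
      else list(a = rep(1, length(d)), B = B, dims = d)
    })
    names(items) <- sp$item
    icc_params(items, specs = sp)
  } else start

  arr <- .item_arrays(template)
  pars <- .item_pars(template)
  gh <- .gh_grid(nodes, m)
  data <- c(list(model = 1L, m = m,
                 obs_unit = as.integer(sv) - 1L,
                 obs_item = match(ds$ITEM, sp$item) - 1L,
                 obs_y = ds$DV,
                 zg = gh$z, logwg = gh$logw, sv_post = sv_post),
            arr)
  parameters <- c(pars, list(post_mu = rep(-1, m), log_post_sd = rep(0.3, m)))

  obj <- TMB::MakeADFun(data = data, parameters = parameters, DLL = "proirt",
                        silent = TRUE)
  best <- new.env(); best$val <- Inf; best$par <- obj$par
  fn <- function(p) {
    v <- obj$fn(p)
    if (is.finite(v) && v < best$val) { best$val <- v; best$par <- p }
    v
  }
  ctrl <- modifyList(list(iter.max = 600, eval.max = 1200,
                          rel.tol = 1e-10), control)
  lower <- rep(-Inf, length(obj$par)); upper <- rep(Inf, length(obj$par))
  nm <- names(obj$par)
  lower[nm == "log_a"] <- -4; upper[nm == "log_a"] <- 3
  lower[nm == "log_dB"] <- -8; upper[nm == "log_dB"] <- 4
  lower[nm == "log_post_sd"] <- -3; upper[nm == "log_post_sd"] <- 3
  opt <- nlminb(obj$par, fn, obj$gr, lower = lower, upper = upper,
                control = ctrl)
  if (!is.finite(best$val))
    stop("ICC estimation failed to reach a finite objective")

  pl <- obj$env$parList()
  icc <- .pars_to_icc(pl, template, sp)
  attr(icc, "n_dim") <- m
  fit <- list(icc = icc, post_mean = pl$post_mu, post_var = exp(2 * pl$log_post_sd),
              ofv = 2 * best$val, convergence = opt$convergence,
              message = opt$message, iterations = opt$iterations,
              excluded_items = excluded, structure = structure)
  if (se) {
    rep <- tryCatch(TMB::sdreport(obj, par.fixed = best$par),
                    error = function(e) NULL)
    if (is.null(rep)) warning("could not produce standard errors")
    else {
      s <- summary(rep, select = "report")
      fit$se <- data.frame(parameter = rownames(s), estimate = s[, 1],
                           se = s[, 2],
                           rse = 100 * abs(s[, 2] / s[, 1]),
                           row.names = NULL)
    }
  }
  class(fit) <- "icc_fit"
  fit
}

#' @export
#' @method print icc_fit
print.icc_fit <- function(x, ...) {
  cat("Pooled ICC fit (", x$structure, "): OFV = ", round(x$ofv, 2),
      ", post-baseline mean = ", paste(round(x$post_mean, 3), collapse = ", "),
      ", var = ", paste(round(x$post_var, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fit a compensatory bidimensional ICC model
#'
#' Convenience wrapper for [fit_icc()] with the bidimensional structure:
#' voiding items on dimension 1, storage items and QoL on dimension 2, and
#' the summary BII loading on both through a compensatory graded response
#' model.  More than two dimensions are unsupported.
#'
#' @inheritParams fit_icc
#' @export
fit_icc_multidim <- function(ds, specs = item_specs(), nodes = 7L,
                             start = NULL, se = FALSE, control = list()) {
  fit_icc(ds, structure = "bidimensional", specs = specs, nodes = nodes,
          start = start, se = se, control = control)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# OFV of the pooled ICC model at fixed parameter values (no optimization);
# used for likelihood-oracle comparisons
.icc_ofv <- function(ds, icc, post_mean, post_var, nodes = 15L,
                     specs = item_specs()) {
  m <- attr(icc, "n_dim")
  icc <- icc[intersect(names(icc), unique(ds$ITEM))]
  class(icc) <- "icc_params"
  ds <- ds[ds$ITEM %in% names(icc), , drop = FALSE]
  sv <- factor(paste(ds$ID, ds$VISIT, sep = "/"),
               levels = unique(paste(ds$ID, ds$VISIT, sep = "/")))
  sv_post <- as.integer(tapply(ds$TIME > 0, sv, any)[levels(sv)])
  gh <- .gh_grid(nodes, m)
  data <- c(list(model = 1L, m = m,
                 obs_unit = as.integer(sv) - 1L,
                 obs_item = match(ds$ITEM, names(icc)) - 1L,
                 obs_y = ds$DV,
                 zg = gh$z, logwg = gh$logw, sv_post = sv_post),
            .item_arrays(icc))
  parameters <- c(.item_pars(icc),
                  list(post_mu = rep(post_mean, length.out = m),
                       log_post_sd = log(sqrt(rep(post_var, length.out = m)))))
  obj <- TMB::MakeADFun(data = data, parameters = parameters,
                        DLL = "proirt", silent = TRUE)
  2 * as.numeric(obj$fn(obj$par))
}
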