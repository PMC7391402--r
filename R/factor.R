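#' Polychoric correlation matrix of the item responses
#'
#' Two-step maximum-likelihood estimate per item pair: univariate thresholds
#' from the marginal category proportions (probit scale), then the latent
#' correlation maximizing the bivariate-normal contingency likelihood.
#' Responses are paired within subject-visit; pairs use the visits at which
#' both items were assessed.
#'
#' @param ds A `pro_dataset`.
#' @param items Optional character vector restricting/ordering the items.
#' @return A correlation matrix (repaired to the nearest positive-definite
#'   matrix, with a warning, if the pairwise estimates are inconsistent).
#' @export
polychoric_matrix <- function(ds, items = NULL) {
  if (is.null(items)) items <- intersect(item_specs()$item, unique(ds$ITEM))
  key <- paste(ds$ID, ds$VISIT, sep = "/")
  wide <- matrix(NA_integer_, length(unique(key)), length(items),
                 dimnames = list(unique(key), items))
  sel <- ds$ITEM %in% items
  wide[cbind(match(key[sel], rownames(wide)), match(ds$ITEM[sel], items))] <-
    ds$DV[sel]
  J <- length(items)
  R <- diag(J)
  for (i in seq_len(J - 1)) {
    for (j in (i + 1):J) {
      ok <- complete.cases(wide[, c(i, j)])
      R[i, j] <- R[j, i] <- .polychoric_pair(wide[ok, i], wide[ok, j])
    }
  }
  dimnames(R) <- list(items, items)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    warning("pairwise polychoric matrix not positive definite; ",
            "using nearest positive-definite repair")
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- list(items, items)
  }
  R
}

# ML polychoric correlation for one pair of ordinal vectors
.polychoric_pair <- function(x, y) {
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  tx <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  ty <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  ax <- c(-Inf, tx, Inf)
  ay <- c(-Inf, ty, Inf)
  nx <- length(ax); ny <- length(ay)
  nll <- function(rho) {
    # bivariate-normal CDF at every threshold grid point
    Phi2 <- matrix(0, nx, ny)
    Phi2[nx, ] <- pnorm(ay)
    Phi2[, ny] <- pnorm(ax)
    S <- matrix(c(1, rho, rho, 1), 2)
    for (i in seq_len(nx - 1)) {
      if (!is.finite(ax[i])) next # -Inf row stays 0
      for (j in seq_len(ny - 1)) {
        if (!is.finite(ay[j])) next
        Phi2[i, j] <- mvtnorm::pmvnorm(upper = c(ax[i], ay[j]), corr = S)
      }
    }
    P <- Phi2[-1, -1, drop = FALSE] - Phi2[-nx, -1, drop = FALSE] -
      Phi2[-1, -ny, drop = FALSE] + Phi2[-nx, -ny, drop = FALSE]
    -sum(tab * log(pmax(P, 1e-12)))
  }
  optimize(nll, c(-0.995, 0.995), tol = 1e-4)$minimum
}

#' Factor analysis of the item correlation structure
#'
#' Dimensionality assessment: maximum-likelihood factor extraction from the
#' inter-item polychoric correlation matrix with varimax orthogonal
#' rotation.  Each item is assigned to the factor with the largest absolute
#' loading; an item is flagged as cross-loading when its two largest
#' absolute loadings differ by less than `cross_margin`, which is what
#' motivates a compensatory IRT model for that item.
#'
#' @param ds A `pro_dataset`.
#' @param n_factors Number of factors (1--3).
#' @param rotation `"varimax"` or `"none"`.
#' @param cross_margin Cross-loading margin on |loading| differences.
#' @return A `factor_solution`: `loadings` (items x factors), `assignment`
#'   (factor index per item), `cross_loading` (logical per item),
#'   `communalities`, and the correlation matrix used.
#' @export
factor_analyze <- function(ds, n_factors, rotation = c("varimax", "none"),
                           cross_margin = 0.15) {
  rotation <- match.arg(rotation)
  stopifnot(n_factors >= 1, n_factors <= 3)
  R <- polychoric_matrix(ds)
  n <- length(unique(paste(ds$ID, ds$VISIT)))
  fa <- factanal(covmat = R, factors = n_factors, rotation = "none",
                 n.obs = n)
  L <- matrix(fa$loadings, nrow(R), n_factors,
              dimnames = list(rownames(R), paste0("F", seq_len(n_factors))))
  if (rotation == "varimax" && n_factors > 1) {
    L <- varimax(L)$loadings
    L <- matrix(L, nrow(R), n_factors,
                dimnames = list(rownames(R), paste0("F", seq_len(n_factors))))
  }
  absL <- abs(L)
  assignment <- apply(absL, 1, which.max)
  cross <- if (n_factors == 1) rep(FALSE, nrow(L)) else
    apply(absL, 1, function(z) diff(sort(z, decreasing = TRUE)[2:1]) < cross_margin)
  structure(list(loadings = L, assignment = assignment,
                 cross_loading = cross, communalities = rowSums(L^2),
                 correlation = R, n_obs = n),
            class = "factor_solution")
}

#' @export
#' @method print factor_solution
print.factor_solution <- function(x, ...) {
  cat("Factor solution (", ncol(x$loadings), " factor(s), n = ", x$n_obs,
      " subject-visits)\n", sep = "")
  df <- as.data.frame(round(x$loadings, 3))
  df$assigned <- colnames(x$loadings)[x$assignment]
  df$cross <- ifelse(x$cross_loading, "*", "")
  print(df)
  invisible(x)
}
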