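#' Item specifications for the BPH-LUTS scales
#'
#' The integrated analysis regards nine items: the seven IPSS items
#' (scored 0--5), the IPSS Quality-of-Life ("bother") question (0--6), and
#' the summary BPH Impact Index treated as a single item with 14 categories
#' (0--13).  IPSS items 1, 3, 5 and 6 (incomplete emptying, intermittency,
#' weak stream, straining) form the voiding subscale; items 2, 4 and 7
#' (frequency, urgency, nocturia) the storage subscale.
#'
#' @param model `"integrated"` for all nine items or `"ipss"` for the seven
#'   IPSS items only.
#' @return A data frame with columns `item`, `ncat` (number of response
#'   categories), `scale` (`IPSS`, `QoL`, `BII`), `subscale` (`voiding`,
#'   `storage`, `none`) and `label`.
#' @export
#' @examples
#' item_specs()
item_specs <- function(model = c("integrated", "ipss")) {
  model <- match.arg(model)
  sp <- data.frame(
    item = c(paste0("IPSS", 1:7), "QoL", "BII"),
    ncat = c(rep(6L, 7), 7L, 14L),
    scale = c(rep("IPSS", 7), "QoL", "BII"),
    subscale = c("voiding", "storage", "voiding", "storage", "voiding",
                 "voiding", "storage", "none", "none"),
    label = c("incomplete emptying", "frequency", "intermittency",
              "urgency", "weak stream", "straining", "nocturia",
              "quality of life", "summary BPH Impact Index"),
    stringsAsFactors = FALSE
  )
  if (model == "ipss") sp <- sp[sp$scale == "IPSS", , drop = FALSE]
  sp
}

#' Latent dimension loadings for a given model structure
#'
#' In the unidimensional structure every item loads on dimension 1.  In the
#' bidimensional structure the IPSS voiding items load on the "voiding"
#' dimension (1), the IPSS storage items and the QoL item on the "storage"
#' dimension (2), and the summary BII loads on both (compensatory item).
#'
#' @param specs An item-specification data frame from [item_specs()].
#' @param structure `"unidimensional"` or `"bidimensional"`.
#' @return A named list mapping item to an integer vector of dimensions.
#' @export
item_dimensions <- function(specs, structure = c("unidimensional", "bidimensional")) {
  structure <- match.arg(structure)
  dims <- lapply(seq_len(nrow(specs)), function(i) {
    if (structure == "unidimensional") return(1L)
    if (specs$scale[i] == "BII") return(c(1L, 2L))
    if (specs$subscale[i] == "voiding") 1L else 2L
  })
  names(dims) <- specs$item
  dims
}

#' Construct a set of item-characteristic-curve parameters
#'
#' Builds an `icc_params` object holding, for every item, its discrimination
#' parameter(s) and ordered difficulty thresholds.  Single-dimension items
#' use the slope--threshold form, with cumulative probability
#' `P(Y >= k) = logistic(a * (psi - b_k))`; compensatory items use the
#' intercept form `P(Y >= k) = logistic(sum_d a_d * psi_d - B_k)`.
#'
#' @param items Named list; each element has fields `a` (numeric vector, one
#'   per loaded dimension, all positive), either `b` (thresholds, single
#'   dimension) or `B` (intercepts, compensatory), and optionally `dims`
#'   (integer vector of loaded dimensions, default `1`).
#' @param specs Item specifications ([item_specs()]); used to validate the
#'   category counts.  Items absent from `specs` are rejected.
#' @return An object of class `icc_params`.
#' @export
icc_params <- function(items, specs = item_specs()) {
  stopifnot(length(items) > 0, !is.null(names(items)))
  out <- lapply(names(items), function(id) {
    it <- items[[id]]
    row <- specs[specs$item == id, , drop = FALSE]
    if (nrow(row) == 0) stop("unknown item: ", id)
    dims <- as.integer(if (is.null(it$dims)) seq_along(it$a) else it$dims)
    if (length(it$a) != length(dims))
      stop("item ", id, ": one discrimination per loaded dimension required")
    if (any(it$a <= 0)) stop("item ", id, ": discriminations must be positive")
    X <- row$ncat - 1L
    if (is.null(it$B)) {
      if (length(dims) != 1)
        stop("item ", id, ": compensatory items need intercepts B")
      b <- it$b
      if (length(b) != X) stop("item ", id, ": expected ", X, " thresholds")
      if (any(diff(b) <= 0)) stop("item ", id, ": thresholds must increase")
      B <- it$a * b
    } else {
      B <- it$B
      if (length(B) != X) stop("item ", id, ": expected ", X, " intercepts")
      if (any(diff(B) <= 0)) stop("item ", id, ": intercepts must increase")
      b <- if (length(dims) == 1) B / it$a else NULL
    }
    list(item = id, a = as.numeric(it$a), dims = dims, b = b, B = B,
         ncat = row$ncat, scale = row$scale, subscale = row$subscale)
  })
  names(out) <- names(items)
  structure(out, class = "icc_params",
            n_dim = max(unlist(lapply(out, `[[`, "dims"))))
}

#' @export
`[.icc_params` <- function(x, i) {
  out <- unclass(x)[i]
  structure(out, class = "icc_params",
            n_dim = max(c(1, unlist(lapply(out, `[[`, "dims")))))
}

#' @export
#' @method print icc_params
print.icc_params <- function(x, ...) {
  cat("Item characteristic curves:", length(x), "items,",
      attr(x, "n_dim"), "latent dimension(s)\n")
  for (it in x) {
    cat(sprintf("  %-6s a = %-22s thresholds in [%.2f, %.2f]\n", it$item,
                paste(signif(it$a, 3), collapse = ", "),
                min(it$B / max(it$a)), max(it$B / max(it$a))))
  }
  invisible(x)
}

#' Read an ICC parameter table
#'
#' Reads a CSV parameter table with columns `item`, `parameter`, `estimate`
#' (and optionally `rse`).  `parameter` is `a` (or `a1`, `a2` for
#' compensatory items) for discriminations and `b1` ... `bX` for difficulty
#' rows.  Under the `incremental` convention, difficulty rows beyond the
#' first are positive increments and the thresholds are their cumulative
#' sums, `b_k = b_1 + sum_{2..k} db`; the `cumulative` convention stores the
#' thresholds directly.
#'
#' @param path CSV file path.
#' @param convention `"incremental"` or `"cumulative"`.
#' @param specs Item specifications; see [icc_params()].
#' @return An `icc_params` object.
#' @export
load_icc_table <- function(path, convention = c("incremental", "cumulative"),
                           specs = item_specs()) {
  convention <- match.arg(convention)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "parameter", "estimate")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  items <- lapply(split(tab, tab$item), function(d) {
    arows <- grepl("^a[0-9]*$", d$parameter)
    brows <- grepl("^b[0-9]+$", d$parameter)
    a <- d$estimate[arows][order(d$parameter[arows])]
    b <- d$estimate[brows][order(as.integer(sub("^b", "", d$parameter[brows])))]
    if (convention == "incremental") {
      if (any(b[-1] <= 0))
        stop("item ", d$item[1], ": non-positive difficulty increment")
      b <- cumsum(b)
    }
    if (any(diff(b) <= 0))
      stop("item ", d$item[1], ": thresholds not strictly increasing")
    if (length(a) > 1) list(a = a, B = b, dims = seq_along(a))
    else list(a = a, b = b)
  })
  icc_params(items[intersect(specs$item, names(items))], specs = specs)
}

#' Write an ICC parameter table
#'
#' Inverse of [load_icc_table()]; always writes the incremental convention
#' for single-dimension items.
#'
#' @param icc An `icc_params` object.
#' @param path Output CSV path.
#' @export
write_icc_table <- function(icc, path) {
  rows <- do.call(rbind, lapply(icc, function(it) {
    if (length(it$dims) == 1) {
      vals <- c(it$a, it$b[1], diff(it$b))
      pars <- c("a", paste0("b", seq_along(it$b)))
    } else {
      vals <- c(it$a, it$B[1], diff(it$B))
      pars <- c(paste0("a", it$dims), paste0("b", seq_along(it$B)))
    }
    data.frame(item = it$item, parameter = pars, estimate = vals,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published reference parameters
#'
#' Parameter estimates for the integrated unidimensional ICC model, the
#' unidimensional longitudinal latent-disability model, and the bidimensional
#' longitudinal model, shipped as plain-text tables.  These are the
#' reproducible surface of the reference Phase II dose-finding study
#' and drive simulation and information ranking without any estimation.
#'
#' Interindividual variabilities are stored as plain standard deviations on
#' the latent scale (lognormal SD on the log scale for `tprog`), i.e. a
#' published "IIV 104.4%" is stored as 0.0104 * 100 = 1.044; correlations as
#' plain coefficients.
#'
#' @param what One of `"icc"`, `"shift"`, `"longitudinal"`,
#'   `"longitudinal_bidim"`.
#' @return `"icc"`: an `icc_params` object; `"shift"`: the post-baseline
#'   latent distribution (mean, var); otherwise a [long_params()] /
#'   [re_spec()] pair in a list.
#' @export
#' @examples
#' reference_params("shift")
reference_params <- function(what = c("icc", "shift", "longitudinal",
                                      "longitudinal_bidim")) {
  what <- match.arg(what)
  ext <- function(f) system.file("extdata", f, package = "proirt", mustWork = TRUE)
  if (what == "icc")
    return(load_icc_table(ext("icc_integrated_unidim.csv"), "incremental"))
  if (what == "shift")
    return(c(mean = -1.53, var = 2.59))
  f <- if (what == "longitudinal") "longitudinal_unidim.csv" else
    "longitudinal_bidim.csv"
  load_long_table(ext(f),
                  structure = if (what == "longitudinal") "unidimensional"
                  else "bidimensional")
}

#' Read a longitudinal parameter table
#'
#' Reads a CSV in the layout of the packaged reference tables (columns
#' `parameter`, `estimate`, optional `unit`).  Values are stored verbatim;
#' rows whose `unit` is `days` (the placebo half-lives) are converted to
#' the package's month time unit (30-day months) on load.
#'
#' @param path CSV file path.
#' @param structure `"unidimensional"` or `"bidimensional"`.
#' @return A list with `params` ([long_params()]) and `re` ([re_spec()]).
#' @export
load_long_table <- function(path,
                            structure = c("unidimensional", "bidimensional")) {
  what <- match.arg(structure)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(tab$unit)) tab$unit <- NA_character_
  days <- !is.na(tab$unit) & tab$unit == "days"
  tab$estimate[days] <- tab$estimate[days] / 30
  v <- setNames(tab$estimate, tab$parameter)
  if (what == "unidimensional") {
    cov <- if ("pvr_on_baseline" %in% names(v))
      data.frame(parameter = "baseline", covariate = "PVR",
                 form = "additive", coef = unname(v["pvr_on_baseline"]),
                 center = 50) else NULL
    p <- long_params(baseline = v["baseline"], pmax = v["pmax"],
                     tprog = v["tprog"], drug = v["drug"], drift = v["drift"],
                     wei = v["wei"], covariates = cov)
    re <- re_spec(sd_baseline = v["iiv_baseline"], sd_pmax = v["iiv_pmax"],
                  sd_drift = v["iiv_drift"], sd_tprog = v["iiv_tprog"],
                  corr = list(baseline_pmax = unname(v["corr_baseline_pmax"]),
                              pmax_drift = unname(v["corr_pmax_drift"])))
  } else {
    p <- long_params(baseline = v[c("baseline_v", "baseline_s")],
                     pmax = v[c("pmax_v", "pmax_s")],
                     tprog = v[c("tprog_v", "tprog_s")],
                     drug = v[c("drug_v", "drug_s")],
                     drift = v["drift"], wei = v["wei"])
    re <- re_spec(sd_baseline = v[c("iiv_baseline_v", "iiv_baseline_s")],
                  sd_pmax = v["iiv_pmax"], sd_drift = v["iiv_drift"],
                  sd_tprog = v["iiv_tprog"],
                  corr = list(baseline_v_s = unname(v["corr_baseline_vs"]),
                              pmax_drift = unname(v["corr_pmax_drift"])))
  }
  list(params = p, re = re)
}
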