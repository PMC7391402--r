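#' Long-format item response dataset
#'
#' The package works on a NONMEM-like long format: one row per observed item
#' response, columns `ID` (subject), `TIME` (months since dosing; baseline
#' is 0), `VISIT` (1-based visit index), `DOSE` (mg; 0 = placebo), `ITEM`,
#' `DV` (integer score), plus optional per-subject covariate columns (e.g.
#' `PVR`, post-void residual volume in mL).  Missing observations are simply
#' absent; there are no placeholder rows.
#'
#' @param df A data frame with the columns above.
#' @param specs Item specifications ([item_specs()]) used for validation.
#' @return The validated data frame with class `pro_dataset`.
#' @export
as_pro_dataset <- function(df, specs = item_specs()) {
  need <- c("ID", "TIME", "VISIT", "DOSE", "ITEM", "DV")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$DV <- as.integer(df$DV)
  df$ID <- as.integer(df$ID)
  df$VISIT <- as.integer(df$VISIT)
  unknown <- setdiff(unique(df$ITEM), specs$item)
  if (length(unknown) > 0)
    stop("unknown item ID(s): ", paste(unknown, collapse = ", "))
  if (any(df$TIME < 0)) stop("times must be non-negative")
  xmax <- setNames(specs$ncat - 1L, specs$item)
  bad <- which(df$DV < 0 | df$DV > xmax[df$ITEM])
  if (length(bad) > 0)
    stop("score out of range (max ", xmax[df$ITEM[bad[1]]], ") in row ",
         bad[1], ": item ", df$ITEM[bad[1]], " = ", df$DV[bad[1]])
  class(df) <- c("pro_dataset", "data.frame")
  df
}

#' Read a long-format dataset from CSV
#'
#' @param path Delimited text file, one observation per row.
#' @param schema Optional named character vector mapping required column
#'   names to the file's column names, e.g. `c(ID = "subject")`.
#' @param specs Item specifications for validation.
#' @return A `pro_dataset`.
#' @export
read_pro_dataset <- function(path, schema = NULL, specs = item_specs()) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df))
        stop("schema column not found in file: ", schema[[std]])
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  as_pro_dataset(df, specs = specs)
}

#' Write a long-format dataset to CSV
#'
#' Lossless export with fixed column order; [read_pro_dataset()] of the
#' result reproduces the dataset.
#'
#' @param ds A `pro_dataset`.
#' @param path Output path.
#' @param header_comment Optional provenance line written as a leading
#'   `#`-comment.
#' @export
write_pro_dataset <- function(ds, path, header_comment = NULL) {
  fixed <- c("ID", "TIME", "VISIT", "DOSE", "ITEM", "DV")
  cols <- c(fixed, setdiff(names(ds), fixed))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste("#", header_comment), con)
  write.csv(as.data.frame(ds)[, cols, drop = FALSE], con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

# observed total scores per subject-visit: total IPSS, QoL, BII
.observed_totals <- function(ds) {
  ipss <- ds[grepl("^IPSS", ds$ITEM), ]
  tot <- aggregate(DV ~ ID + VISIT + TIME, data = ipss, FUN = sum)
  names(tot)[names(tot) == "DV"] <- "IPSS"
  for (sc in c("QoL", "BII")) {
    sub <- ds[ds$ITEM == sc, c("ID", "VISIT", sc = "DV")]
    if (nrow(sub) > 0) {
      names(sub)[3] <- sc
      tot <- merge(tot, sub, by = c("ID", "VISIT"), all.x = TRUE)
    } else tot[[sc]] <- NA_integer_
  }
  tot[order(tot$ID, tot$VISIT), ]
}
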