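#' Read and write count series
#'
#' A count series is stored as plain text: either a headerless single
#' column (one count per line) or a CSV/TSV with a header, from which a
#' named column is extracted. Entries must parse as non-negative
#' integers; offending lines are reported by number.
#'
#' @param path file path.
#' @param column optional column name for delimited files with a header.
#' @return `read_count_series`: an integer vector. `write_count_series`:
#'   the path, invisibly.
#' @examples
#' f <- tempfile()
#' write_count_series(c(3L, 1L, 4L), f)
#' read_count_series(f)
#' @export
read_count_series <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(column)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty series file: ", path, call. = FALSE)
    vals <- suppressWarnings(as.numeric(trimws(lines)))
    bad <- which(is.na(vals) | vals != floor(vals))
    if (length(bad))
      stop("non-integer entries at line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path,
           call. = FALSE)
    neg <- which(vals < 0)
    if (length(neg))
      stop("negative counts at line(s) ",
           paste(utils::head(neg, 5), collapse = ", "), " of ", path,
           call. = FALSE)
    return(as.integer(vals))
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!column %in% names(df))
    stop("column '", column, "' not found in ", path, " (available: ",
         paste(names(df), collapse = ", "), ")", call. = FALSE)
  vals <- df[[column]]
  bad <- which(is.na(vals) | vals != floor(vals))
  if (length(bad))
    stop("non-integer entries in column '", column, "' at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (any(vals < 0))
    stop("negative counts in column '", column, "' at data line(s) ",
         paste(utils::head(which(vals < 0), 5), collapse = ", "),
         call. = FALSE)
  as.integer(vals)
}

#' @rdname read_count_series
#' @param y integer vector of counts.
#' @export
write_count_series <- function(y, path) {
  y <- check_series(y, min_len = 1L)
  writeLines(as.character(y), path)
  invisible(path)
}

#' Compare coefficient-family fits on one series
#'
#' Runs CLS plus CML under each requested coefficient family and tabulates
#' estimates with AIC/BIC, flagging the minimum-BIC family — the model
#' comparison workflow used when fitting real count data.
#'
#' @param y a count series.
#' @param families coefficient families to try.
#' @param innovation innovation family for the CML likelihoods.
#' @param link an `odinar_link`.
#' @return A list of class `odinar_comparison`: `fits` (named list),
#'   `table` (data.frame of estimates and criteria) and `best_bic`.
#' @export
compare_phi_families <- function(y, families = PHI_FAMILIES,
                                 innovation = "poisson",
                                 link = link_linear()) {
  families <- match.arg(families, PHI_FAMILIES, several.ok = TRUE)
  y <- check_series(y)
  fits <- list(cls = cls_fit(y, link))
  rows <- list(data.frame(model = "CLS", t(coef(fits$cls)),
                          AIC = NA_real_, BIC = NA_real_,
                          converged = fits$cls$converged))
  for (fam in families) {
    sp <- odinar_spec(phi = fam, innovation = innovation, link = link)
    f <- tryCatch(cml_fit(y, sp), error = function(e) NULL)
    nm <- paste0("cml_", fam)
    if (is.null(f)) next
    fits[[nm]] <- f
    ic <- information_criteria(f$value, length(coef(f)), length(y))
    rows[[length(rows) + 1L]] <- data.frame(
      model = nm, t(coef(f)), AIC = ic[["AIC"]], BIC = ic[["BIC"]],
      converged = f$converged)
  }
  tab <- do.call(rbind, rows)
  cml_rows <- tab[!is.na(tab$BIC) & tab$converged, , drop = FALSE]
  best <- if (nrow(cml_rows)) cml_rows$model[which.min(cml_rows$BIC)] else NA
  structure(list(fits = fits, table = tab, best_bic = best),
            class = "odinar_comparison")
}

#' @export
print.odinar_comparison <- function(x, ...) {
  cat("Coefficient-family comparison (CLS + CML fits)\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) if (is.numeric(v)) round(v, 4) else v)
  print(tab, row.names = FALSE)
  cat("minimum-BIC model:", x$best_bic, "\n")
  invisible(x)
}
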