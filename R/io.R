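#' Read a long-format MRM intensity CSV
#'
#' Expects a UTF-8 CSV with header columns \code{sample_id}, \code{Q1},
#' \code{Q3}, \code{area} (case-insensitive; areas in arbitrary units with a
#' decimal point). Rows are matched to configured transitions later, at fit
#' time, by nominal m/z within a matching window; duplicate
#' (sample, transition) rows are summed with a warning there.
#'
#' @param path CSV file path.
#' @return data.frame of class \code{"intensity_table"} with normalized
#'   column names.
#' @export
read_intensity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty intensity file: ", path)
  names(df) <- tolower(names(df))
  need <- c("sample_id", "q1", "q3", "area")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("intensity file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  suppressWarnings(area_num <- as.numeric(df$area))
  if (anyNA(area_num) && !all(is.na(df$area) == is.na(area_num))) {
    bad <- which(is.na(area_num) & !is.na(df$area))
    stop("non-numeric area at data row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  df$area <- area_num
  df <- df[need]
  names(df) <- c("sample_id", "Q1", "Q3", "area")
  class(df) <- c("intensity_table", "data.frame")
  df
}

#' Write fitted isotopomer fractions as CSV
#'
#' One row per sample; one column per isotopomer in canonical order, named
#' \code{<mol>_<bits>} (e.g. \code{glu_01111}), plus \code{residual_norm} and
#' \code{n_masked}. Provenance (package version, molecule, matrix variant,
#' matrix checksum, solver) is embedded in commented header lines so a file
#' identifies the computation that produced it; identical inputs produce
#' byte-identical files.
#'
#' @param fit an \code{\link{isotopomer_fit}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fractions_csv <- function(fit, path) {
  stopifnot(inherits(fit, "isotopomer_fit"))
  mol <- fit$molecule
  prefix <- substr(mol$name, 1, 3)
  co <- fit$coefficients
  colnames(co) <- paste0(prefix, "_", colnames(co))
  df <- data.frame(sample_id = rownames(co),
                   signif(co, 6),
                   residual_norm = signif(fit$residual_norm, 6),
                   n_masked = fit$n_masked,
                   check.names = FALSE, row.names = NULL)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# mrmiso %s", as.character(utils::packageVersion("mrmiso"))),
    sprintf("# molecule=%s na_corrected=%s solver=%s matrix_md5=%s",
            mol$name, attr(fit$matrix, "na_corrected"), fit$method,
            matrix_md5(fit$matrix))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

matrix_md5 <- function(A) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(rownames(A), colnames(A),
               sprintf("%.17g", as.numeric(unclass(A)))), tmp)
  unname(tools::md5sum(tmp))
}

#' Read fractions written by \code{write_fractions_csv}
#'
#' @param path CSV file path.
#' @return data.frame with the sample rows and fraction columns.
#' @export
read_fractions_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
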