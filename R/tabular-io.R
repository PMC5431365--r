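#' @include biomarker-table.R
NULL

# delimiters tried, in order, when none is forced
.knownDelims <- c(",", "\t", ";")

.detectDelim <- function(headerLine) {
  counts <- vapply(.knownDelims, function(d) {
    hits <- gregexpr(d, headerLine, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) 0L else length(hits)
  }, integer(1))
  if (all(counts == 0L)) return(",")
  .knownDelims[which.max(counts)]
}

#' Read a subject-level biochemistry table
#'
#' Reads a delimited text file (CSV/TSV, RFC-4180-style quoting) with one row
#' per subject into a [BiomarkerTable-class]. The first column is taken as the
#' subject identifier unless `idColumn` says otherwise; all remaining columns
#' must be numeric apart from configured missing codes.
#'
#' @param path file to read.
#' @param delim field delimiter; `NULL` (default) auto-detects from
#'   `","`, tab or `";"` on the header line.
#' @param missingCodes character values treated as missing cells. The default
#'   covers the codes common in clinical biochemistry tables.
#' @param decimal decimal separator, `"."` or `","`; with `","` the file is
#'   assumed to come from a European laboratory export and comma decimals are
#'   converted (only usable with a non-comma `delim`).
#' @param idColumn name or index of the subject-identifier column; default 1.
#' @param columnMap optional named character vector renaming file columns to
#'   canonical variable names, e.g. `c("CoQ" = "Q10 nmol/g")` (name =
#'   desired variable, value = column header in the file); columns not
#'   mentioned keep their header names.
#' @param units optional named character vector of unit strings for the
#'   (renamed) variables.
#' @return A [BiomarkerTable-class]. Rows keep file order. Negative values
#'   are permitted but flagged with a warning (concentrations and activities
#'   are physically non-negative).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,CoQ,CS", "P1,185,132", "P2,NA,90", "P3,310,"), tf)
#' bt <- readBiomarkerTable(tf)
#' sum(is.na(measurements(bt)))  # 2
#' @export
readBiomarkerTable <- function(path, delim = NULL,
                               missingCodes = c("", "NA", "ND", "n.d."),
                               decimal = ".", idColumn = 1L,
                               columnMap = NULL, units = NULL) {
  .assertString(path, "path")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- .detectDelim(header)
  if (decimal == "," && delim == ",")
    stop("decimal ',' requires a non-comma delimiter", call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim, dec = decimal,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  if (is.character(idColumn)) {
    idColumn <- match(idColumn, names(raw))
    if (is.na(idColumn)) stop("idColumn not found in header", call. = FALSE)
  }
  ids <- trimws(raw[[idColumn]])
  if (anyDuplicated(ids)) {
    stop("duplicate subject identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  dat <- raw[, -idColumn, drop = FALSE]
  vars <- names(dat)
  if (!is.null(columnMap)) {
    hit <- match(vars, columnMap)
    vars[!is.na(hit)] <- names(columnMap)[hit[!is.na(hit)]]
  }
  values <- matrix(NA_real_, nrow = nrow(dat), ncol = ncol(dat),
                   dimnames = list(ids, vars))
  for (j in seq_along(dat)) {
    cell <- trimws(dat[[j]])
    miss <- cell %in% missingCodes | is.na(cell)
    if (decimal == ",") cell <- gsub(",", ".", cell, fixed = TRUE)
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric value \"%s\" in row %d, column \"%s\"",
                   cell[i], i, vars[j]), call. = FALSE)
    }
    num[miss] <- NA_real_
    values[, j] <- num
  }
  nNeg <- sum(values < 0, na.rm = TRUE)
  if (nNeg > 0) {
    warning(sprintf("%d negative value(s) found; %s", nNeg,
                    "concentrations/activities are physically non-negative"),
            call. = FALSE)
  }
  BiomarkerTable(values, units = units)
}

#' Write a BiomarkerTable to CSV
#'
#' Missing cells are written as empty strings; the subject identifier goes in
#' the first column (`id`). The output is readable by [readBiomarkerTable()]
#' (values round-trip to full double precision).
#'
#' @param table a [BiomarkerTable-class].
#' @param path output file path.
#' @param delim field delimiter (default `","`).
#' @return Invisibly, `path`.
#' @export
writeBiomarkerTable <- function(table, path, delim = ",") {
  stopifnot(is(table, "BiomarkerTable"))
  v <- measurements(table)
  txt <- matrix("", nrow = nrow(v), ncol = ncol(v))
  ok <- !is.na(v)
  txt[ok] <- formatC(v[ok], digits = 17, format = "g")
  df <- data.frame(id = rownames(v) %||% character(0),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) df[[colnames(v)[j]]] <- txt[, j]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = delim, row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}
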