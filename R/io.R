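# Delimited-table readers and writers. All tables are comma-separated UTF-8
# with a header row and ISO-8601 dates; writers use a fixed column order and
# fixed float formatting so outputs are byte-comparable across runs.

.schemas <- list(
  counts = c(site_id = "character", species_id = "character", date = "date",
             count = "integer", scheme = "character"),
  events = c(site_id = "character", date = "date", scheme = "character"),
  presences = c(species_id = "character", hectad_easting = "integer",
                hectad_northing = "integer", year = "integer"),
  temperatures = c(site_id = "character", date = "date", tmean = "numeric"),
  elevations = c(easting = "integer", northing = "integer",
                 elevation_m = "numeric"),
  traits = c(species_id = "character", taxon_group = "character",
             voltinism = "character", habitat_class = "character")
)

#' Read and validate a delimited table
#'
#' @param path CSV file path.
#' @param schema either the name of a built-in schema (`"counts"`,
#'   `"events"`, `"presences"`, `"temperatures"`, `"elevations"`,
#'   `"traits"`) or a named character vector of column types
#'   (`"character"`, `"integer"`, `"numeric"`, `"date"`).
#' @return validated, typed data frame.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1 && schema %in% names(.schemas))
    schema <- .schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(names(schema), names(raw))
  extra <- setdiff(names(raw), names(schema))
  if (length(missing) || length(extra))
    stop("schema mismatch in ", basename(path),
         if (length(missing)) paste0("; missing column(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")))
  out <- raw[, names(schema), drop = FALSE]
  for (col in names(schema)) {
    v <- out[[col]]
    out[[col]] <- switch(schema[[col]],
      character = v,
      integer = {
        conv <- suppressWarnings(as.integer(v))
        bad <- which(is.na(conv) & !is.na(v) & nzchar(v))
        if (length(bad)) stop("unparseable integer in ", basename(path),
                              ", column ", col, ", line(s) ",
                              paste(bad + 1L, collapse = ", "))
        conv
      },
      numeric = {
        conv <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(conv) & !is.na(v) & nzchar(v))
        if (length(bad)) stop("unparseable number in ", basename(path),
                              ", column ", col, ", line(s) ",
                              paste(bad + 1L, collapse = ", "))
        conv
      },
      date = {
        conv <- as.Date(v, format = "%Y-%m-%d")
        bad <- which(is.na(conv))
        if (length(bad)) stop("unparseable ISO-8601 date in ", basename(path),
                              ", column ", col, ", line(s) ",
                              paste(bad + 1L, collapse = ", "))
        conv
      },
      stop("unknown schema type: ", schema[[col]]))
  }
  out
}

#' Write a table with stable formatting
#'
#' Numeric columns are written with 10 significant digits and dates as
#' ISO-8601, so identical inputs give byte-identical files.
#'
#' @param df data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (col in names(out)) {
    v <- out[[col]]
    if (inherits(v, "Date")) out[[col]] <- format(v, "%Y-%m-%d")
    else if (is.double(v)) out[[col]] <- ifelse(is.na(v), "",
                                                formatC(v, digits = 10,
                                                        format = "g"))
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
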