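#' Read and validate a species trait table
#'
#' Reads a CSV or TSV (UTF-8, header row) keyed by a `species` column,
#' normalizes species names (spaces to underscores), and validates the
#' column conventions used throughout the pipeline: `prevalence_*` columns
#' must lie in `[0, 1]`, `pct_*` columns in `[0, 100]`, count-like columns
#' (`n_*`, `*_count`, `*_papers`) must be nonnegative, and `iucn_rank`
#' must take values 1-5. Violations raise typed errors naming the column
#' and offending species.
#'
#' @param file path to a delimited text file; the delimiter is taken from
#'   the extension (`.tsv` = tab, otherwise comma) unless `sep` is given.
#' @param sep optional field separator override.
#' @return a validated `data.frame`.
#' @export
read_species_data <- function(file, sep = NULL) {
  if (!file.exists(file)) stop("species table not found: ", file)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  validate_species_data(df)
}

#' @rdname read_species_data
#' @param data a data.frame to validate in place of reading a file.
#' @export
validate_species_data <- function(data) {
  data <- as.data.frame(data)
  if (!"species" %in% names(data))
    stop("species table must contain a 'species' column")
  data$species <- normalize_taxa(data$species)
  if (anyDuplicated(data$species))
    stop("duplicated species: ",
         paste(unique(data$species[duplicated(data$species)]),
               collapse = ", "))
  check_range <- function(col, lo, hi) {
    v <- data[[col]]
    bad <- !is.na(v) & (v < lo | v > hi)
    if (any(bad))
      stop("column '", col, "' outside [", lo, ", ", hi, "] for species: ",
           paste(data$species[bad], collapse = ", "), call. = FALSE)
  }
  for (col in grep("^prevalence_", names(data), value = TRUE))
    check_range(col, 0, 1)
  for (col in grep("^pct_", names(data), value = TRUE))
    check_range(col, 0, 100)
  counts <- grep("^n_|_count$|_papers$", names(data), value = TRUE)
  for (col in counts) check_range(col, 0, Inf)
  if ("iucn_rank" %in% names(data)) {
    v <- data$iucn_rank
    bad <- !is.na(v) & !(v %in% 1:5)
    if (any(bad))
      stop("iucn_rank must be in 1..5; offending species: ",
           paste(data$species[bad], collapse = ", "))
  }
  data
}

## Exclusion log: one record per excluded species with a machine-readable
## reason code. Kept as a data.frame and serialized to exclusions.log.
.exclusion_record <- function(species, reason, detail = "") {
  data.frame(species = species, reason = reason, detail = detail,
             stringsAsFactors = FALSE)
}

.write_exclusions <- function(exclusions, path) {
  if (is.null(exclusions) || nrow(exclusions) == 0) {
    writeLines("# no exclusions", path)
    return(invisible(path))
  }
  writeLines(c("# species\treason\tdetail",
               paste(exclusions$species, exclusions$reason,
                     exclusions$detail, sep = "\t")), path)
  invisible(path)
}
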