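# CSV schemas shared by the generator, the readers and the pipeline.
csv_schemas <- function() {
  list(
    rainfall = c(date = "Date", mm = "numeric"),
    soil = c(plot = "character", sand = "numeric", gravel = "numeric",
             cobble = "numeric", boulder = "numeric",
             large_boulder = "numeric"),
    veg = c(plot = "character", year = "integer", round = "integer",
            total_cover = "numeric", herb_cover = "numeric",
            grass_cover = "numeric", n_species = "integer"),
    traps = c(plot = "character", year = "integer", round = "integer",
              start_date = "Date", taxon = "character", count = "integer"),
    taxa = c(taxon = "character", trophic_group = "character",
             ground_dwelling = "logical"))
}

coerce_schema <- function(df, schema, file) {
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[names(schema)]
  for (col in names(schema)) {
    x <- df[[col]]
    out <- switch(schema[[col]],
      Date = as.Date(as.character(x)),
      numeric = suppressWarnings(as.numeric(x)),
      integer = suppressWarnings(as.integer(x)),
      logical = as.logical(x),
      character = as.character(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad))
      stop(sprintf("%s: column '%s' not parseable as %s at row %d",
                   file, col, schema[[col]], bad[1]), call. = FALSE)
    df[[col]] <- out
  }
  df
}

#' Read one of the study CSV files
#'
#' Validates headers and column types and fails with a row-numbered
#' message on malformed input. Dates are ISO-8601.
#'
#' @param path file path.
#' @param what one of `"rainfall"`, `"soil"`, `"veg"`, `"traps"`, `"taxa"`.
#' @return a data.frame in the canonical column order.
#' @export
read_study_csv <- function(path, what) {
  schema <- csv_schemas()[[match.arg(what, names(csv_schemas()))]]
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  coerce_schema(df, schema, basename(path))
}

#' Write a synthetic study bundle to CSV files
#'
#' Writes `rainfall.csv`, `soil.csv`, `veg.csv`, `traps.csv`, `taxa.csv`
#' and `truth.json` under `dir`. A write/read round trip reproduces all
#' values exactly.
#'
#' @param study a `sim_study` from [gen_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    for (col in names(df)) if (inherits(df[[col]], "Date"))
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  }
  wr(study$rainfall, "rainfall"); wr(study$soil, "soil")
  wr(study$veg, "veg"); wr(study$traps, "traps"); wr(study$taxa, "taxa")
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir directory containing the CSV files.
#' @return a list with `rainfall`, `soil`, `veg`, `traps`, `taxa` and, if
#'   present, `truth`.
#' @export
read_study <- function(dir) {
  out <- lapply(setNames(nm = names(csv_schemas())), function(what)
    read_study_csv(file.path(dir, paste0(what, ".csv")), what))
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}
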