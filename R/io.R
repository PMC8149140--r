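# Typed CSV ingest for the four study tables (fish, gut, isotope, community).
# Dialect: comma-separated, UTF-8, header required, "." decimal, missing = "".

.schemas <- list(
  fish = list(
    cols = c(fish_id = "character", population_id = "character",
             status = "character", total_length_cm = "numeric",
             weight_g = "numeric", age = "integer", pass_number = "integer"),
    required = c("fish_id", "population_id", "status", "total_length_cm", "weight_g")
  ),
  gut = list(
    cols = c(fish_id = "character", population_id = "character",
             total_length_cm = "numeric", category = "character",
             volume_pct = "numeric"),
    required = c("fish_id", "population_id", "total_length_cm", "category",
                 "volume_pct")
  ),
  isotope = list(
    cols = c(sample_id = "character", group = "character", taxon = "character",
             population_id = "character", d13C = "numeric", d15N = "numeric",
             c_to_n = "numeric"),
    required = c("sample_id", "group", "taxon", "population_id", "d13C", "d15N")
  ),
  community = list(
    cols = c(site_id = "character", taxon = "character", count = "integer",
             area_m2 = "numeric"),
    required = c("site_id", "taxon", "count", "area_m2")
  )
)

#' Fullness marker used in the long gut table
#'
#' In `gut.csv` each fish carries one row with `category == "_fullness"` whose
#' `volume_pct` is the visually estimated total gut fullness (0--100); the
#' remaining rows apportion that fullness among food categories by volume.
#' @export
FULLNESS_CATEGORY <- "_fullness"

.coerce_col <- function(x, type, col) {
  x[x == ""] <- NA
  out <- switch(type,
    character = as.character(x),
    numeric   = suppressWarnings(as.numeric(x)),
    integer   = {
      v <- suppressWarnings(as.numeric(x))
      if (any(!is.na(v) & v != round(v)))
        stop(sprintf("column '%s': non-integer value", col), call. = FALSE)
      as.integer(round(v))
    }
  )
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("column '%s': cannot parse value '%s' (row %d)",
                 col, x[bad[1]], bad[1]), call. = FALSE)
  out
}

#' Read and validate one of the study tables
#'
#' @param path path to a CSV file.
#' @param schema one of `"fish"`, `"gut"`, `"isotope"`, `"community"`.
#' @return a validated `data.frame` with the schema's columns, row order
#'   preserved.
#' @details Column names must match the schema exactly (order free). Every row
#'   is checked against the record invariants (positive lengths and weights,
#'   per-fish gut volumes summing to the recorded fullness, finite per-mil
#'   values, non-negative counts); violations raise an error naming the column
#'   or row.
#' @export
read_table <- function(path, schema = c("fish", "gut", "isotope", "community")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sc <- .schemas[[schema]]
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  missing_cols <- setdiff(names(sc$cols), names(raw))
  if (length(missing_cols))
    stop(sprintf("schema '%s': missing column(s): %s", schema,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- as.data.frame(
    lapply(stats::setNames(names(sc$cols), names(sc$cols)),
           function(cl) .coerce_col(raw[[cl]], sc$cols[[cl]], cl)),
    stringsAsFactors = FALSE)
  validate_records(df, schema)
  df
}

#' Write a study table as CSV
#'
#' Inverse of [read_table()]: round-tripping preserves records exactly up to
#' numeric formatting. Missing values are written as empty strings.
#' @param df validated data frame.
#' @param path output path.
#' @param schema schema name (see [read_table()]).
#' @export
write_table <- function(df, path, schema = c("fish", "gut", "isotope", "community")) {
  schema <- match.arg(schema)
  validate_records(df, schema)
  df <- df[, names(.schemas[[schema]]$cols), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

.row_err <- function(i, msg) {
  stop(sprintf("row %d: %s", i, msg), call. = FALSE)
}

#' Validate records against their type invariants
#'
#' @param df data frame shaped like the output of [read_table()].
#' @param schema schema name.
#' @return `df`, invisibly, if valid; otherwise an error identifying the first
#'   offending row.
#' @export
validate_records <- function(df, schema = c("fish", "gut", "isotope", "community")) {
  schema <- match.arg(schema)
  sc <- .schemas[[schema]]
  for (cl in sc$required) {
    i <- which(is.na(df[[cl]]))
    if (length(i)) .row_err(i[1], sprintf("missing required value in '%s'", cl))
  }
  if (schema == "fish") {
    i <- which(df$total_length_cm <= 0)
    if (length(i)) .row_err(i[1], "total_length_cm must be > 0")
    i <- which(!is.na(df$weight_g) & df$weight_g <= 0)
    if (length(i)) .row_err(i[1], "weight_g must be > 0")
    i <- which(!is.na(df$age) & df$age < 0)
    if (length(i)) .row_err(i[1], "age must be >= 0")
    i <- which(!df$status %in% c("purebred", "introgressed"))
    if (length(i)) .row_err(i[1], "status must be 'purebred' or 'introgressed'")
    i <- which(!is.na(df$pass_number) & df$pass_number < 1)
    if (length(i)) .row_err(i[1], "pass_number must be >= 1")
  } else if (schema == "gut") {
    i <- which(df$volume_pct < 0 | df$volume_pct > 100)
    if (length(i)) .row_err(i[1], "volume_pct must be in [0, 100]")
    for (id in unique(df$fish_id)) {
      sub <- df[df$fish_id == id, ]
      full <- sub$volume_pct[sub$category == FULLNESS_CATEGORY]
      if (length(full) != 1)
        stop(sprintf("fish '%s': expected exactly one '%s' row", id,
                     FULLNESS_CATEGORY), call. = FALSE)
      items <- sub$volume_pct[sub$category != FULLNESS_CATEGORY]
      if (abs(sum(items) - full) > 1e-9)
        stop(sprintf("fish '%s': item volumes sum to %g but fullness is %g",
                     id, sum(items), full), call. = FALSE)
      if (full == 0 && length(items) > 0 && any(items > 0))
        stop(sprintf("fish '%s': empty gut must carry no items", id),
             call. = FALSE)
    }
  } else if (schema == "isotope") {
    i <- which(!is.finite(df$d13C) | !is.finite(df$d15N))
    if (length(i)) .row_err(i[1], "d13C/d15N must be finite")
    i <- which(!df$group %in% c("consumer", "baseline_bmi", "producer"))
    if (length(i))
      .row_err(i[1], "group must be consumer/baseline_bmi/producer")
    i <- which(!is.na(df$c_to_n) & df$c_to_n <= 0)
    if (length(i)) .row_err(i[1], "c_to_n must be > 0")
  } else if (schema == "community") {
    i <- which(df$count < 0)
    if (length(i)) .row_err(i[1], "count must be >= 0")
    i <- which(df$area_m2 <= 0)
    if (length(i)) .row_err(i[1], "area_m2 must be > 0")
  }
  invisible(df)
}
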