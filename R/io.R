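# Plant-level data input with total validation: every malformed row yields a
# located diagnostic; nothing is silently dropped or coerced.

.canonical_pollination <- c(c = "C", hp = "HP")
.canonical_nutrient <- c("0n" = "0N", "05n" = "05N", "0.5n" = "05N",
                         "1n" = "1N", "2n" = "2N")
.canonical_site <- c(low_water = "low_water", high_water = "high_water",
                     low = "low_water", high = "high_water",
                     garden = "garden")

.numeric_fields <- c("year", "flowering_start", "flowering_end",
                     "flowering_duration", "plant_height", "n_flowers",
                     "corolla_size", "corolla_tube_size",
                     "corolla_tube_length", "fruit_production",
                     "seeds_per_fruit", "seeds_per_plant")
.count_fields <- c("n_flowers", "fruit_production", "seeds_per_plant")

#' Read and validate a plant-level dataset
#'
#' Reads a delimited text file with one row per plant and validates it
#' against the package's data model: categorical design factors are
#' normalized to canonical tokens (`C`/`HP`, `0N`/`05N`/`1N`/`2N`,
#' `low_water`/`high_water`/`garden`), trait and fitness columns must be
#' numeric, counts non-negative, and `flowering_duration` must equal
#' `flowering_end - flowering_start` whenever all three are present.  All
#' problems are collected and reported together with their row numbers.
#'
#' @param path Path to a delimited text file with a header row.
#' @param traits Character vector of trait columns that must be present
#'   (e.g. [trait_spec()] output), or `NULL` to require only the core
#'   columns.
#' @param sep Field separator: `","` (default) or `"\t"`.
#' @return A `data.frame` of validated plant records.
#' @export
read_plant_data <- function(path, traits = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  required <- unique(c("pollination", "seeds_per_plant", traits))
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  problems <- character(0)
  note <- function(rows, msg) {
    problems <<- c(problems,
                   sprintf("row %s: %s", paste(rows, collapse = ", "), msg))
  }

  tok <- tolower(trimws(as.character(dat$pollination)))
  bad <- which(!tok %in% names(.canonical_pollination))
  if (length(bad) > 0L) note(bad, "pollination level not one of C, HP")
  dat$pollination <- unname(.canonical_pollination[tok])

  if ("nutrient" %in% names(dat)) {
    tok <- tolower(trimws(as.character(dat$nutrient)))
    bad <- which(!tok %in% names(.canonical_nutrient))
    if (length(bad) > 0L) note(bad, "unrecognized nutrient level")
    dat$nutrient <- unname(.canonical_nutrient[tok])
  }
  if ("site" %in% names(dat)) {
    tok <- tolower(trimws(as.character(dat$site)))
    bad <- which(!tok %in% names(.canonical_site))
    if (length(bad) > 0L) note(bad, "unrecognized site label")
    dat$site <- unname(.canonical_site[tok])
  }

  for (col in intersect(c(.numeric_fields, traits), names(dat))) {
    raw <- dat[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & trimws(as.character(raw)) != "")
    if (length(bad) > 0L) note(bad, paste0("non-numeric value in ", col))
    dat[[col]] <- num
  }
  for (col in intersect(.count_fields, names(dat))) {
    bad <- which(dat[[col]] < 0)
    if (length(bad) > 0L) note(bad, paste0(col, " is negative"))
  }
  if ("seeds_per_fruit" %in% names(dat)) {
    bad <- which(dat$seeds_per_fruit < 0)
    if (length(bad) > 0L) note(bad, "seeds_per_fruit is negative")
  }
  if (all(c("flowering_start", "flowering_end", "flowering_duration") %in%
          names(dat))) {
    full <- complete.cases(dat[c("flowering_start", "flowering_end",
                                 "flowering_duration")])
    bad <- which(full & abs(dat$flowering_end - dat$flowering_start -
                            dat$flowering_duration) > 1e-8)
    if (length(bad) > 0L) {
      note(bad, "flowering_duration != flowering_end - flowering_start")
    }
  }
  if (length(problems) > 0L) {
    stop("invalid plant data:\n  ", paste(problems, collapse = "\n  "))
  }
  dat
}

#' Write an analysis result table to delimited text
#'
#' Serializes any of the package's result objects (gradient, contrast,
#' strength, ANOVA tables, pollen-limitation results, or a plain data frame)
#' with a stable column order and full double precision, so that
#' [read_result_table()] reproduces the values to at least 12 significant
#' digits.
#'
#' @param x Result object or data frame; must be finite-valued.
#' @param path Output file path.
#' @param format `"csv"` (default), `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  if (any(vapply(df[num], function(v) any(!is.finite(v) & !is.na(v)),
                 logical(1)))) {
    stop("result table contains non-finite values; refusing to write")
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    switch(format,
      csv = write.csv(df, path, row.names = FALSE),
      tsv = write.table(df, path, sep = "\t", row.names = FALSE,
                        quote = TRUE),
      json = jsonlite::write_json(df, path, dataframe = "rows",
                                  auto_unbox = TRUE, digits = NA, na = "null")
    )
    TRUE
  }, error = function(e) {
    stop("cannot write ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @return A `data.frame`.
#' @export
read_result_table <- function(path, format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  switch(format,
    csv = read.csv(path, stringsAsFactors = FALSE),
    tsv = read.csv(path, sep = "\t", stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  )
}
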