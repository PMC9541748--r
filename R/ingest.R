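#' Default column schema for breeding-record CSV files
#'
#' Maps the canonical field names used throughout the package to the column
#' names expected in an input file. Supply a modified copy to
#' [read_breeding_records()] when your file uses different headers.
#'
#' @return Named character vector: canonical field -> column name.
#' @export
#' @examples
#' breeding_schema()
breeding_schema <- function() {
  c(
    individual_id = "individual_id",
    population    = "population",
    sex           = "sex",
    birth_year    = "birth_year",
    breed_year    = "breed_year",
    age           = "age",
    clutch_size   = "clutch_size",
    clutch_type   = "clutch_type",
    polygamous    = "polygamous"
  )
}

.integer_fields <- c("birth_year", "breed_year", "age", "clutch_size")

#' Read long-format breeding records from CSV
#'
#' One row per individual x breeding year. Categorical fields are validated
#' (`sex` in female/male, `clutch_type` in first/second/replacement,
#' `polygamous` logical) and integer fields are parsed strictly: a
#' non-integer entry fails with the offending row number rather than being
#' silently coerced to `NA`.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Named character vector mapping canonical field names to the
#'   file's column names; defaults to [breeding_schema()].
#' @return A tibble of breeding records with canonical column names, in file
#'   row order.
#' @export
read_breeding_records <- function(path, schema = breeding_schema()) {
  if (!file.exists(path)) {
    stop("breeding-record file not found: ", path, call. = FALSE)
  }
  full <- breeding_schema()
  full[names(schema)] <- schema
  schema <- full
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(stats::setNames(raw[unname(schema)], names(schema)))
  for (f in .integer_fields) {
    v <- trimws(out[[f]])
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed) | parsed != floor(parsed))
    if (length(bad) > 0) {
      stop(sprintf("column '%s' (%s) is not an integer on row %d (value '%s')",
                   schema[[f]], f, bad[1], v[bad[1]]), call. = FALSE)
    }
    out[[f]] <- as.integer(parsed)
  }
  out$polygamous <- .parse_logical(out$polygamous, schema[["polygamous"]])
  .validate_records(out)
  out
}

.parse_logical <- function(v, colname) {
  v <- tolower(trimws(v))
  map <- c("true" = TRUE, "t" = TRUE, "1" = TRUE, "yes" = TRUE,
           "false" = FALSE, "f" = FALSE, "0" = FALSE, "no" = FALSE)
  bad <- which(!v %in% names(map))
  if (length(bad) > 0) {
    stop(sprintf("column '%s' is not logical on row %d (value '%s')",
                 colname, bad[1], v[bad[1]]), call. = FALSE)
  }
  unname(map[v])
}

.validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  req <- names(breeding_schema())
  missing <- setdiff(req, names(records))
  if (length(missing) > 0) {
    stop("records are missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(unique(records$sex), c("female", "male"))
  if (length(bad_sex) > 0) {
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(records$clutch_type),
                      c("first", "second", "replacement"))
  if (length(bad_type) > 0) {
    stop("invalid clutch_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$age < 1)) stop("age must be >= 1", call. = FALSE)
  if (any(records$clutch_size < 0)) {
    stop("clutch_size must be >= 0", call. = FALSE)
  }
  invisible(records)
}

#' Construct an empty filter report
#'
#' @return A `ric_filter_report` list of exclusion counters.
#' @export
filter_report <- function() {
  structure(
    list(
      n_input                    = 0L,
      n_excluded_second          = 0L,
      n_excluded_replacement     = 0L,
      n_excluded_polygamous      = 0L,
      n_individuals_dropped_gap  = 0L,
      n_individuals_dropped_short = 0L,
      per_population_n           = list()
    ),
    class = "ric_filter_report"
  )
}

#' @export
print.ric_filter_report <- function(x, ...) {
  cat("Breeding-record filter report\n")
  cat(sprintf("  records in:            %d\n", x$n_input))
  cat(sprintf("  excluded second:       %d\n", x$n_excluded_second))
  cat(sprintf("  excluded replacement:  %d\n", x$n_excluded_replacement))
  cat(sprintf("  excluded polygamous:   %d\n", x$n_excluded_polygamous))
  cat(sprintf("  individuals dropped (interior gap): %d\n",
              x$n_individuals_dropped_gap))
  cat(sprintf("  individuals dropped (series < min): %d\n",
              x$n_individuals_dropped_short))
  if (length(x$per_population_n) > 0) {
    cat("  retained individuals per population:\n")
    for (p in names(x$per_population_n)) {
      cat(sprintf("    %s: %d\n", p, x$per_population_n[[p]]))
    }
  }
  invisible(x)
}

#' Apply record-level exclusion rules
#'
#' Keeps only first clutches of non-polygamous pairs: second clutches,
#' replacement clutches (laid after early-season failure) and any breeding
#' attempt flagged polygamous are removed, since those attempts reflect a
#' different investment process than a single first clutch.
#'
#' @param records Tibble of breeding records (see [read_breeding_records()]).
#' @param report Optional existing `ric_filter_report` to update.
#' @return List with `records` (retained rows) and `report`.
#' @export
apply_exclusions <- function(records, report = filter_report()) {
  .validate_records(records)
  report$n_input <- report$n_input + nrow(records)
  is_second      <- records$clutch_type == "second"
  is_replacement <- records$clutch_type == "replacement"
  is_poly        <- records$polygamous & !is_second & !is_replacement
  report$n_excluded_second      <- report$n_excluded_second + sum(is_second)
  report$n_excluded_replacement <-
    report$n_excluded_replacement + sum(is_replacement)
  report$n_excluded_polygamous  <- report$n_excluded_polygamous + sum(is_poly)
  keep <- !(is_second | is_replacement | is_poly)
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Population-year mean clutch sizes
#'
#' The environmental baseline used for mean-centring: the average first
#' clutch laid in each population in each year, computed over all first
#' clutch records (including individuals later dropped for gaps or short
#' series, so that the baseline uses the full population sample).
#'
#' @param records First-clutch breeding records.
#' @return Tibble with `population`, `breed_year`, `mean_clutch`,
#'   `n_records`.
#' @export
population_year_means <- function(records) {
  .validate_records(records)
  records |>
    dplyr::group_by(.data$population, .data$breed_year) |>
    dplyr::summarise(
      mean_clutch = mean(.data$clutch_size),
      n_records   = dplyr::n(),
      .groups     = "drop"
    ) |>
    dplyr::arrange(.data$population, .data$breed_year)
}

#' Assemble gap-free per-individual clutch-size series
#'
#' An individual's series must cover strictly consecutive breeding years:
#' any interior gap (a year in which the bird was alive but no breeding was
#' recorded) drops the individual entirely, because an unobserved year
#' cannot be distinguished from breeding outside the study area. Series
#' shorter than `min_length` are dropped as well: a Fourier decomposition
#' needs at least three points to carry an oscillatory signal.
#'
#' @param records First-clutch records (after [apply_exclusions()]).
#' @param min_length Minimum series length retained (default 3).
#' @param report Optional `ric_filter_report` to update.
#' @return List with `series` (nested tibble, one row per retained
#'   individual, list-columns `years`, `ages`, `clutch`, `centred`) and
#'   `report`. `centred` is `NULL` per individual until [centre_series()].
#' @export
build_series <- function(records, min_length = 3, report = filter_report()) {
  .validate_records(records)
  dup <- records |>
    dplyr::count(.data$individual_id, .data$breed_year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf(
      "duplicate (individual, year) after exclusions: %s in %d",
      dup$individual_id[1], dup$breed_year[1]), call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$individual_id, .data$breed_year)
  nested <- records |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      population       = .data$population[1],
      sex              = .data$sex[1],
      birth_year       = .data$birth_year[1],
      first_breed_year = .data$breed_year[1],
      n                = dplyr::n(),
      gap_free         = all(diff(.data$breed_year) == 1L),
      years            = list(.data$breed_year),
      ages             = list(.data$age),
      clutch           = list(as.numeric(.data$clutch_size)),
      .groups          = "drop"
    )
  report$n_individuals_dropped_gap <-
    report$n_individuals_dropped_gap + sum(!nested$gap_free)
  nested <- nested[nested$gap_free, , drop = FALSE]
  short <- nested$n < min_length
  report$n_individuals_dropped_short <-
    report$n_individuals_dropped_short + sum(short)
  nested <- nested[!short, , drop = FALSE]
  nested$gap_free <- NULL
  nested$mean_individual_clutch <-
    vapply(nested$clutch, mean, numeric(1))
  nested$centred <- rep(list(NULL), nrow(nested))
  tab <- table(nested$population)
  for (p in names(tab)) {
    prev <- report$per_population_n[[p]]
    report$per_population_n[[p]] <-
      (if (is.null(prev)) 0L else prev) + as.integer(tab[[p]])
  }
  list(series = nested, report = report)
}

#' Mean-centre clutch series against population-year averages
#'
#' Subtracts the population-year mean clutch size from every observation,
#' removing shared inter-annual environmental variation (density- or
#' climate-driven good and bad years) from each individual trajectory.
#'
#' @param series Nested series tibble from [build_series()].
#' @param means Population-year means from [population_year_means()].
#' @return `series` with the `centred` list-column populated; absolute
#'   values are unchanged.
#' @export
centre_series <- function(series, means) {
  key <- paste(means$population, means$breed_year, sep = "\r")
  lookup <- stats::setNames(means$mean_clutch, key)
  series$centred <- purrr::pmap(
    list(series$population, series$years, series$clutch),
    function(pop, yrs, cl) {
      k <- paste(pop, yrs, sep = "\r")
      hit <- match(k, names(lookup))
      if (anyNA(hit)) {
        i <- which(is.na(hit))[1]
        stop(sprintf("no population-year mean for (%s, %d)", pop, yrs[i]),
             call. = FALSE)
      }
      cl - unname(lookup[hit])
    }
  )
  series
}

#' Mean individual clutch size
#'
#' Lifetime average clutch size of one individual, used downstream as an
#' individual-quality covariate.
#'
#' @param clutch Numeric vector of absolute clutch sizes (length >= 1).
#' @return Arithmetic mean, in eggs.
#' @export
#' @examples
#' mean_individual_clutch(c(7, 9, 8))
mean_individual_clutch <- function(clutch) {
  if (length(clutch) < 1) stop("empty clutch series", call. = FALSE)
  mean(clutch)
}

#' Filter, assemble and centre breeding records in one step
#'
#' Convenience wrapper: record-level exclusions, population-year means
#' (computed from all retained first-clutch records, before series-level
#' drops), gap-free series assembly, and mean-centring.
#'
#' @inheritParams build_series
#' @return List with `series`, `means` and `report`.
#' @export
prepare_series <- function(records, min_length = 3) {
  excl <- apply_exclusions(records)
  means <- population_year_means(excl$records)
  built <- build_series(excl$records, min_length = min_length,
                        report = excl$report)
  built$series <- centre_series(built$series, means)
  list(series = built$series, means = means, report = built$report)
}

#' Flatten a nested series tibble to long format
#'
#' @param series Nested series tibble.
#' @return Long tibble, one row per individual-year, with absolute and
#'   centred clutch values.
#' @export
series_to_long <- function(series) {
  has_centred <- !vapply(series$centred, is.null, logical(1))
  series$centred[!has_centred] <-
    lapply(series$n[!has_centred], function(n) rep(NA_real_, n))
  series |>
    dplyr::select("individual_id", "population", "sex", "birth_year",
                  "mean_individual_clutch", "years", "ages", "clutch",
                  "centred") |>
    tidyr::unnest(c("years", "ages", "clutch", "centred")) |>
    dplyr::rename(breed_year = "years", age = "ages",
                  clutch_size = "clutch", centred_clutch = "centred")
}
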