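#' @keywords internal
#' @useDynLib rarecast, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Embedded Violence Project fixtures -----------------------------------------
## Event-occurrence times in days since 1966-08-01 (173 events, 1966 - early
## 2020) and annual counts 1966-2019.  The two tables come from the same
## database but are not mutually consistent (171 vs 173 events); see
## fixture_consistency_report().

.event_times_fixture <- c(
  0, 101, 447, 595, 979, 1512, 2128, 2150, 2351, 3136, 3631, 3848, 4007,
  4040, 4336, 4932, 5071, 5100, 5391, 5550, 5752, 5848, 5859, 6027, 6055,
  6275, 6496, 6538, 6557, 6563, 6800, 7319, 7567, 7865, 8016, 8081, 8201,
  8438, 8717, 9194, 9200, 9215, 9223, 9228, 9354, 9400, 9564, 9587, 9825,
  9860, 9928, 9976, 9981, 9988, 10179, 10370, 10467, 10573, 10723, 10778,
  10853, 11333, 11359, 11437, 11452, 11535, 11553, 11553, 11609, 11904,
  11944, 11944, 11987, 12043, 12089, 12136, 12194, 12279, 12317, 12555,
  12573, 12599, 12747, 12812, 13011, 13349, 13482, 13531, 13588, 13841,
  13980, 13997, 14095, 14096, 14105, 14262, 14419, 14474, 14530, 14661,
  14796, 14860, 15089, 15093, 15156, 15163, 15197, 15294, 15361, 15573,
  15577, 15785, 15789, 15813, 15942, 16005, 16062, 16073, 16100, 16222,
  16431, 16460, 16496, 16671, 16729, 16779, 16794, 16846, 16923, 17017,
  17055, 17101, 17150, 17200, 17359, 17452, 17603, 17841, 17870, 17945,
  17988, 18006, 18006, 18089, 18108, 18201, 18226, 18302, 18410, 18440,
  18486, 18559, 18675, 18709, 18718, 18797, 18813, 18825, 18881, 18907,
  18947, 19021, 19066, 19076, 19157, 19179, 19285, 19347, 19348, 19375,
  19474, 19474, 19555)

.annual_counts_fixture <- c(
  2, 1, 1, 1, 1, 0, 2, 1, 0, 1, 1, 3, 1, 0, 3, 2, 3, 3, 4, 1, 1, 1, 3, 2,
  1, 5, 4, 6, 2, 3, 2, 4, 4, 8, 3, 4, 1, 4, 3, 4, 4, 4, 5, 5, 5, 4, 6, 5,
  3, 6, 5, 7, 8, 8)

.fixture_origin <- as.Date("1966-08-01")

## Constructors and validators ------------------------------------------------

#' Event-time series
#'
#' An ordered set of event occurrence times measured in days since a calendar
#' origin, together with the end of the observation window.
#'
#' @param event_times numeric vector of days since `origin_date`,
#'   non-decreasing, all `>= 0`.  Ties are allowed (two events on one day).
#' @param origin_date calendar date of day 0 (`Date` or coercible string).
#' @param observation_end end of the observation window in days since origin;
#'   defaults to the last event time.
#' @return an object of class `event_series`.
#' @examples
#' ev <- event_series(c(0, 101, 450), "1966-08-01")
#' @export
event_series <- function(event_times, origin_date = .fixture_origin,
                         observation_end = NULL) {
  event_times <- as.numeric(event_times)
  origin_date <- as.Date(origin_date)
  if (is.na(origin_date)) stop("event_series: missing or invalid origin_date")
  if (anyNA(event_times)) stop("event_series: NA event times")
  if (is.unsorted(event_times)) {
    stop("unsorted_event_times: event times must be non-decreasing")
  }
  if (length(event_times) && event_times[1] < 0) {
    stop("event_series: negative event time")
  }
  if (is.null(observation_end)) {
    observation_end <- if (length(event_times)) max(event_times) else 0
  }
  if (length(event_times) && max(event_times) > observation_end) {
    stop("event_series: event time beyond observation_end")
  }
  structure(list(event_times = event_times, origin_date = origin_date,
                 observation_end = as.numeric(observation_end)),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d events over [0, %g] days from %s\n",
              length(x$event_times), x$observation_end,
              format(x$origin_date)))
  invisible(x)
}

#' Annual count series
#'
#' Non-negative integer counts for consecutive calendar years.
#'
#' @param counts integer vector of non-negative annual counts.
#' @param start_year first calendar year.
#' @return an object of class `annual_counts`.
#' @examples
#' annual_counts(c(2, 1, 0), 1966)
#' @export
annual_counts <- function(counts, start_year) {
  counts <- as.numeric(counts)
  if (!length(counts)) stop("annual_counts: empty counts")
  if (anyNA(counts)) stop("annual_counts: NA counts")
  if (any(counts < 0)) stop("negative_count: counts must be non-negative")
  start_year <- as.integer(start_year)
  structure(list(counts = counts, start_year = start_year,
                 years = seq(start_year, by = 1L,
                             length.out = length(counts))),
            class = "annual_counts")
}

#' @export
print.annual_counts <- function(x, ...) {
  cat(sprintf("<annual_counts> %d years %d-%d, total %g events\n",
              length(x$counts), x$start_year, max(x$years), sum(x$counts)))
  invisible(x)
}

## Fixture loaders ------------------------------------------------------------

#' Embedded event-time fixture
#'
#' The 173 recorded U.S. mass-shooting dates (Violence Project), expressed in
#' days since the first event on 1966-08-01.  The first event defines the
#' process origin (time 0); the last falls in early 2020.
#'
#' @return an [event_series] with origin 1966-08-01.
#' @export
mass_shooting_events <- function() {
  event_series(.event_times_fixture, .fixture_origin)
}

#' Embedded annual-count fixture
#'
#' Annual numbers of U.S. mass shootings 1966-2019 (Violence Project), with
#' the option to append the single event recorded for 2020.
#'
#' @param include_2020 if `TRUE`, append the 2020 count of 1.
#' @return an [annual_counts] object starting in 1966.
#' @export
mass_shooting_counts <- function(include_2020 = FALSE) {
  cts <- .annual_counts_fixture
  if (include_2020) cts <- c(cts, 1)
  annual_counts(cts, 1966L)
}

## Conversions and splits -----------------------------------------------------

#' Day offset of 1 January of a year relative to an origin date
#' @keywords internal
year_start_offset <- function(year, origin_date) {
  as.numeric(as.Date(sprintf("%d-01-01", year)) - as.Date(origin_date))
}

#' Bin an event series into annual counts
#'
#' Each event is assigned to the calendar year of `origin_date + t` days
#' (real date arithmetic, leap years included).  Years from the origin year
#' through the year of the last event are returned; the first calendar year
#' is typically partial.
#'
#' @param events an [event_series].
#' @return an [annual_counts] object.
#' @export
events_to_annual_counts <- function(events) {
  stopifnot(inherits(events, "event_series"))
  if (is.null(events$origin_date) || is.na(events$origin_date)) {
    stop("events_to_annual_counts: missing origin_date")
  }
  y0 <- as.integer(format(events$origin_date, "%Y"))
  if (!length(events$event_times)) {
    return(annual_counts(0, y0))
  }
  yrs <- as.integer(format(events$origin_date + floor(events$event_times),
                           "%Y"))
  y1 <- max(yrs)
  tab <- tabulate(yrs - y0 + 1L, nbins = y1 - y0 + 1L)
  annual_counts(tab, y0)
}

#' Truncate an event series at a new observation end
#'
#' Drops events after `observation_end` days; used e.g. to restrict the
#' fixture to events through the end of a training year.
#'
#' @param events an [event_series].
#' @param observation_end new window end in days since origin.
#' @return an [event_series].
#' @export
truncate_events <- function(events, observation_end) {
  stopifnot(inherits(events, "event_series"))
  event_series(events$event_times[events$event_times <= observation_end],
               events$origin_date, observation_end)
}

#' Time-ordered train/test split of annual counts
#'
#' @param counts an [annual_counts] object.
#' @param last_train_year final year of the training set; must lie strictly
#'   inside the year range so both sets are non-empty.
#' @return list with `train` and `test`, both [annual_counts].
#' @export
split_by_year <- function(counts, last_train_year) {
  stopifnot(inherits(counts, "annual_counts"))
  yrs <- counts$years
  if (last_train_year < yrs[1] || last_train_year >= max(yrs)) {
    stop("split_by_year: last_train_year outside the year range")
  }
  tr <- counts$counts[yrs <= last_train_year]
  te <- counts$counts[yrs > last_train_year]
  list(train = annual_counts(tr, yrs[1]),
       test = annual_counts(te, last_train_year + 1L))
}

## CSV round-trip -------------------------------------------------------------

#' Read/write annual counts and event series as CSV
#'
#' Annual counts use columns `year,count`; event series use `index,t_days`
#' with the origin date stored in a `# origin:` comment line.  Writing then
#' reading reproduces the object exactly.
#'
#' @param x object to write.
#' @param path file path.
#' @return the read object, or (for writers) `path` invisibly.
#' @name series_csv
NULL

#' @rdname series_csv
#' @export
write_counts_csv <- function(x, path) {
  stopifnot(inherits(x, "annual_counts"))
  utils::write.csv(data.frame(year = x$years, count = x$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname series_csv
#' @export
read_counts_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("year", "count") %in% names(d))) {
    stop("malformed_csv: expected columns year,count")
  }
  if (anyNA(d$year) || anyNA(d$count)) stop("malformed_csv: missing values")
  if (any(d$count < 0)) stop("negative_count: counts must be non-negative")
  if (any(diff(d$year) != 1)) stop("malformed_csv: years not consecutive")
  annual_counts(d$count, d$year[1])
}

#' @rdname series_csv
#' @export
write_events_csv <- function(x, path) {
  stopifnot(inherits(x, "event_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# origin: %s", format(x$origin_date)), con)
  writeLines(sprintf("# observation_end: %g", x$observation_end), con)
  utils::write.csv(data.frame(index = seq_along(x$event_times),
                              t_days = x$event_times),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname series_csv
#' @export
read_events_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  origin <- sub("^# origin: *", "", hdr[grepl("^# origin:", hdr)])
  oe <- sub("^# observation_end: *", "",
            hdr[grepl("^# observation_end:", hdr)])
  if (!length(origin)) stop("malformed_csv: missing origin metadata line")
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("index", "t_days") %in% names(d))) {
    stop("malformed_csv: expected columns index,t_days")
  }
  if (anyNA(d$t_days)) stop("malformed_csv: missing values")
  if (is.unsorted(d$t_days)) {
    stop("unsorted_event_times: event times must be non-decreasing")
  }
  event_series(d$t_days, origin,
               if (length(oe)) as.numeric(oe) else NULL)
}

## Consistency report ---------------------------------------------------------

#' Consistency report for the two embedded fixtures
#'
#' The annual-count table (171 events, 1966-2019) and the event-time table
#' (173 events, last event converting to early 2020) disagree.  Both are kept
#' verbatim; this report quantifies the differences instead of reconciling
#' them.
#'
#' @param path optional path; if given, the report is also written as JSON.
#' @return a list with totals and the per-year difference table.
#' @export
fixture_consistency_report <- function(path = NULL) {
  ev <- mass_shooting_events()
  ac <- mass_shooting_counts()
  binned <- events_to_annual_counts(ev)
  yrs <- ac$years
  b <- binned$counts[match(yrs, binned$years)]
  b[is.na(b)] <- 0
  rep <- list(
    n_events_time_table = length(ev$event_times),
    n_events_count_table = sum(ac$counts),
    last_event_year = max(binned$years),
    count_table_years = range(yrs),
    per_year = data.frame(year = yrs, count_table = ac$counts,
                          binned_from_events = b,
                          difference = b - ac$counts)
  )
  rep$n_years_differing <- sum(rep$per_year$difference != 0)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  rep
}
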