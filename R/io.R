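#' Construct and validate point-count records
#'
#' A point-count record is one species detection within one 5-minute interval
#' at one observation point on one date. Surveys follow a fixed design: six
#' 1-minute samples at 5-minute spacing over 30 minutes, detections within an
#' 85 m radius. `distance_m` may be `NA` for heard-only detections; such
#' records are kept for abundance but excluded from distance analyses.
#'
#' @param df Data frame with columns `site`, `area` (`"nestbox"` or
#'   `"control"`), `point_id`, `date` (ISO-8601), `interval` (1-6), `species`,
#'   `count` (>= 0) and optionally `distance_m` (<= 85 when present).
#' @param max_distance Observation radius in meters (default 85).
#' @return A validated `pointcount` data frame (`date` as `Date`, `area` as a
#'   factor with levels nestbox, control).
#' @export
as_pointcounts <- function(df, max_distance = 85) {
  req <- c("site", "area", "point_id", "date", "interval", "species", "count")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"distance_m" %in% names(df)) df$distance_m <- NA_real_

  df$site <- as.character(df$site)
  df$point_id <- as.character(df$point_id)
  df$species <- as.character(df$species)
  df$distance_m <- as.numeric(df$distance_m)

  area <- as.character(df$area)
  bad <- which(!area %in% c("nestbox", "control"))
  if (length(bad) > 0)
    abort_field(bad[1], "area",
                sprintf("unknown area value '%s' (must be nestbox or control)",
                        area[bad[1]]))
  df$area <- factor(area, levels = c("nestbox", "control"))

  d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  bad <- which(is.na(d))
  if (length(bad) > 0)
    abort_field(bad[1], "date", "not an ISO-8601 (YYYY-MM-DD) date")
  df$date <- d

  iv <- suppressWarnings(as.integer(df$interval))
  bad <- which(is.na(iv) | iv < 1L | iv > 6L)
  if (length(bad) > 0)
    abort_field(bad[1], "interval", "interval out of range (must be 1..6)")
  df$interval <- iv

  ct <- suppressWarnings(as.integer(df$count))
  bad <- which(is.na(ct) | ct < 0L)
  if (length(bad) > 0)
    abort_field(bad[1], "count", "count must be a non-negative integer")
  df$count <- ct

  bad <- which(!is.na(df$distance_m) &
                 (df$distance_m < 0 | df$distance_m > max_distance))
  if (length(bad) > 0)
    abort_field(bad[1], "distance_m",
                sprintf("distance must be in [0, %g] m", max_distance))

  df <- df[, c(req, "distance_m")]
  class(df) <- c("pointcount", "data.frame")
  df
}

#' Read or write point-count records as CSV
#'
#' @param path CSV file path; header row mandatory, columns as in
#'   [as_pointcounts()].
#' @return `read_pointcounts()` returns a validated `pointcount` data frame;
#'   `write_pointcounts()` returns `path` invisibly. Writing then reading
#'   reproduces the records field-for-field.
#' @export
read_pointcounts <- function(path) {
  as_pointcounts(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_pointcounts
#' @param records A `pointcount` data frame.
#' @export
write_pointcounts <- function(records, path) {
  records <- as_pointcounts(as.data.frame(records))
  out <- as.data.frame(records)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Breeding-season time periods
#'
#' The analysis bins survey dates into three 4-week phenological periods:
#' early (territory establishment and laying), middle (first broods fledging)
#' and late (second broods fledging). Defaults are the 2009 season boundaries;
#' both are configurable so the pipeline generalizes to other seasons.
#'
#' @param early,middle,late Length-2 character or `Date` vectors giving the
#'   inclusive start and end of each period.
#' @return A `period_table` data frame with columns `period`, `start`, `end`.
#' @export
#' @examples
#' season_periods()
season_periods <- function(early = c("2009-04-22", "2009-05-22"),
                           middle = c("2009-05-23", "2009-06-20"),
                           late = c("2009-06-21", "2009-07-19")) {
  p <- data.frame(period = factor(c("early", "middle", "late"),
                                  levels = c("early", "middle", "late")),
                  start = as.Date(c(early[1], middle[1], late[1])),
                  end = as.Date(c(early[2], middle[2], late[2])))
  if (any(p$start > p$end)) stop("period start after end", call. = FALSE)
  if (any(p$start[-1] != p$end[-3] + 1))
    stop("periods must be contiguous and ordered", call. = FALSE)
  class(p) <- c("period_table", "data.frame")
  p
}

#' Assign dates to breeding-season periods
#'
#' @param dates `Date` (or ISO-8601 character) vector.
#' @param periods A `period_table` from [season_periods()].
#' @return Factor of periods (levels early, middle, late). Dates outside all
#'   ranges are an error: every analyzed date must fall in exactly one period.
#' @export
#' @examples
#' assign_period(as.Date("2009-05-01"))  # early
assign_period <- function(dates, periods = season_periods()) {
  dates <- as.Date(dates)
  idx <- findInterval(as.numeric(dates), as.numeric(periods$start))
  ok <- idx >= 1 & idx <= nrow(periods) & !is.na(dates)
  ok[ok] <- dates[ok] <= periods$end[idx[ok]]
  if (!all(ok))
    stop("date(s) outside all periods: ",
         paste(format(unique(dates[!ok])), collapse = ", "), call. = FALSE)
  periods$period[idx]
}

#' Construct and validate sentinel-prey transects
#'
#' One transect is five immobilized larvae pinned at 5 m spacing; each station
#' outcome is recorded after ~6 h of exposure as removed (`TRUE`) or still
#' present (`FALSE`). Transects belong to one of three groups - `control`
#' (no-box vineyard half), `nestbox_random` (random points in the box half) or
#' `active_nest` (within 25 m of an occupied box) - and to a spatial block
#' (site x vineyard half).
#'
#' @param df Data frame with columns `site`, `block`, `group` and either
#'   station columns `o1`..`o5` (logical/0-1) or a `removed` count plus
#'   `n_stations`.
#' @return A `sentinel` data frame with columns `site`, `block`, `group`
#'   (factor, reference level control), `removed`, `n_stations`, `o1`..`o5`.
#' @export
as_sentinel <- function(df) {
  req <- c("site", "block", "group")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  grp <- as.character(df$group)
  bad <- which(!grp %in% c("control", "nestbox_random", "active_nest"))
  if (length(bad) > 0)
    abort_field(bad[1], "group", sprintf("unknown group '%s'", grp[bad[1]]))
  df$group <- factor(grp, levels = c("control", "nestbox_random", "active_nest"))
  df$site <- as.character(df$site)
  df$block <- as.character(df$block)

  ocols <- paste0("o", 1:5)
  if (all(ocols %in% names(df))) {
    for (oc in ocols) {
      v <- df[[oc]]
      if (!all(v %in% c(0, 1, TRUE, FALSE)))
        abort_field(which(!v %in% c(0, 1))[1], oc, "outcomes must be 0/1")
      df[[oc]] <- as.logical(v)
    }
    df$n_stations <- 5L
    df$removed <- as.integer(rowSums(as.matrix(df[ocols])))
  } else {
    if (!all(c("removed", "n_stations") %in% names(df)))
      stop("need either station columns o1..o5 or removed + n_stations",
           call. = FALSE)
    df$n_stations <- as.integer(df$n_stations)
    df$removed <- as.integer(df$removed)
    bad <- which(is.na(df$removed) | df$removed < 0 |
                   df$removed > df$n_stations)
    if (length(bad) > 0)
      abort_field(bad[1], "removed", "removed count must be in [0, n_stations]")
    for (k in 1:5) df[[ocols[k]]] <- k <= df$removed  # canonical fill
  }
  df <- df[, c("site", "block", "group", "removed", "n_stations", ocols)]
  class(df) <- c("sentinel", "data.frame")
  df
}

#' Read or write sentinel transects as CSV
#'
#' @param path CSV path with columns `site,block,group,o1,o2,o3,o4,o5`.
#' @return `read_sentinel()` returns a validated `sentinel` data frame.
#' @export
read_sentinel <- function(path) {
  as_sentinel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sentinel
#' @param transects A `sentinel` data frame.
#' @export
write_sentinel <- function(transects, path) {
  transects <- as_sentinel(as.data.frame(transects))
  out <- as.data.frame(transects)[, c("site", "block", "group",
                                      paste0("o", 1:5))]
  for (oc in paste0("o", 1:5)) out[[oc]] <- as.integer(out[[oc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate nest-monitoring records
#'
#' One record per nesting attempt in a box pair: occupant species, first-egg
#' date, clutch size, and the weekly check dates on which the nest was active
#' (contained eggs and/or live nestlings).
#'
#' @param df Data frame with columns `box_pair_id`, `species`,
#'   `first_egg_date`, `clutch_size`, `active_weeks` (semicolon-separated
#'   ISO dates in CSV form).
#' @return A `nestrecord` data frame; `active_weeks` is a list column of
#'   `Date` vectors.
#' @export
as_nests <- function(df) {
  req <- c("box_pair_id", "species", "first_egg_date", "clutch_size")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df$box_pair_id <- as.character(df$box_pair_id)
  df$species <- as.character(df$species)
  df$first_egg_date <- as.Date(as.character(df$first_egg_date))
  df$clutch_size <- as.integer(df$clutch_size)
  bad <- which(is.na(df$clutch_size) | df$clutch_size < 0)
  if (length(bad) > 0)
    abort_field(bad[1], "clutch_size", "clutch size must be >= 0")
  aw <- df$active_weeks %||% rep("", nrow(df))
  if (!is.list(aw))
    aw <- lapply(strsplit(as.character(aw), ";", fixed = TRUE),
                 function(x) as.Date(x[nzchar(x)]))
  df$active_weeks <- aw
  class(df) <- c("nestrecord", "data.frame")
  df
}

#' @rdname as_nests
#' @param path CSV path.
#' @export
read_nests <- function(path) {
  as_nests(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname as_nests
#' @param nests A `nestrecord` data frame.
#' @export
write_nests <- function(nests, path) {
  out <- as.data.frame(as_nests(as.data.frame(nests)))
  out$active_weeks <- vapply(out$active_weeks,
                             function(x) paste(format(x), collapse = ";"), "")
  out$first_egg_date <- format(out$first_egg_date)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
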