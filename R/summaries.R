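# Sample key: one 30-minute observation = one point on one date.
sample_key <- function(records) {
  interaction(records$site, records$area, records$point_id,
              format(records$date), drop = TRUE, lex.order = TRUE, sep = "|")
}

record_guild <- function(records, guilds) classify_guild(records$species, guilds)

filter_records <- function(records, guilds = NULL, guild = NULL,
                           species = NULL, exclude_species = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(guild)) {
    if (is.null(guilds)) stop("guild filter requires a guild table", call. = FALSE)
    keep <- keep & (as.character(record_guild(records, guilds)) %in% guild)
  }
  if (!is.null(species)) keep <- keep & records$species %in% species
  if (!is.null(exclude_species)) keep <- keep & !records$species %in% exclude_species
  records[keep, , drop = FALSE]
}

#' Species richness of one 30-minute observation sample
#'
#' Number of distinct species detected across the six 5-minute intervals of a
#' sample, optionally restricted to one diet guild.
#'
#' @param sample `pointcount` records belonging to a single observation sample.
#' @param guild Optional guild filter (`"I"`, `"O"` or `"G"`).
#' @param guilds Guild lookup table, required when `guild` is given.
#' @return Integer species count (0 for an empty sample).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' pc <- simulate_pointcounts(cfg)
#' s1 <- pc[sample_id(pc) == sample_id(pc)[1], ]
#' richness(s1)
#' richness(s1, guild = "I", guilds = vineyard_guilds())
richness <- function(sample, guild = NULL, guilds = NULL) {
  sample <- filter_records(sample, guilds, guild)
  length(unique(sample$species[sample$count > 0]))
}

#' Mean abundance per 5-minute interval for one observation sample
#'
#' Total count matching the filter divided by the number of intervals in the
#' sample design (not the number of intervals with detections), so all-zero
#' intervals dilute the mean as they did in the field.
#'
#' @inheritParams richness
#' @param intervals Intervals per sample (default 6).
#' @param species Restrict to these species codes.
#' @param exclude_species Drop these species codes (e.g. the focal species for
#'   the non-bluebird insectivore response).
#' @return Mean count per interval (0 for an empty sample).
#' @export
interval_abundance <- function(sample, intervals = 6, guild = NULL,
                               species = NULL, exclude_species = NULL,
                               guilds = NULL) {
  sample <- filter_records(sample, guilds, guild, species, exclude_species)
  sum(sample$count) / intervals
}

#' Sample identifiers for point-count records
#'
#' @param records A `pointcount` data frame.
#' @return Factor with one level per observation sample
#'   (site x area x point x date).
#' @export
sample_id <- function(records) sample_key(records)

#' Built-in response definitions
#'
#' The seven response variables of the analysis: overall and insectivore
#' species richness per 30-minute sample, and per-interval abundance of all
#' birds, the focal species, non-focal insectivores, omnivores and granivores.
#'
#' @param focal Focal species code (default `"WEBL"`).
#' @return Named list of response definitions accepted by [replicate_means()].
#' @export
response_definitions <- function(focal = "WEBL") {
  list(
    richness = list(stat = "richness"),
    insectivore_richness = list(stat = "richness", guild = "I"),
    total_abundance = list(stat = "abundance"),
    bluebird_abundance = list(stat = "abundance", species = focal),
    nonbluebird_insectivore_abundance =
      list(stat = "abundance", guild = "I", exclude_species = focal),
    omnivore_abundance = list(stat = "abundance", guild = "O"),
    granivore_abundance = list(stat = "abundance", guild = "G"))
}

#' Treatment x site x period replicate means
#'
#' Reduces raw point-count records to the replicate means entering the
#' bootstrap test: the per-sample statistic (richness or per-interval
#' abundance) is computed for every 30-minute sample, then averaged over the
#' samples falling in each treatment x site x period cell. In the full design
#' each treatment yields 6 replicates (2 sites x 3 periods); a single-site
#' input yields 3 and is flagged as a partial design.
#'
#' @param records A `pointcount` data frame spanning both treatment areas.
#' @param responses Character vector naming entries of
#'   [response_definitions()], or a list of such definitions.
#' @param guilds Guild lookup table.
#' @param periods A [season_periods()] table.
#' @param intervals Intervals per sample (default 6).
#' @param focal Focal species code used by the built-in definitions.
#' @return Data frame (class `replicate_means`) with columns `response`,
#'   `area`, `site`, `period`, `value`. Empty cells are kept as `NA` with a
#'   warning, never silently dropped. Attribute `partial_design` is `TRUE`
#'   when fewer than 2 sites or 3 periods are present.
#' @export
#' @examples
#' pc <- simulate_pointcounts(sim_config(seed = 1))
#' rm6 <- replicate_means(pc, "bluebird_abundance")
#' subset(rm6, area == "nestbox")
replicate_means <- function(records, responses = names(response_definitions()),
                            guilds = vineyard_guilds(),
                            periods = season_periods(), intervals = 6,
                            focal = "WEBL") {
  stopifnot(nrow(records) > 0)
  defs <- if (is.character(responses)) {
    all_defs <- response_definitions(focal)
    unknown <- setdiff(responses, names(all_defs))
    if (length(unknown) > 0)
      stop("unknown response(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    all_defs[responses]
  } else responses

  key <- sample_key(records)
  roster <- !duplicated(key)
  frame <- data.frame(key = key[roster],
                      site = records$site[roster],
                      area = records$area[roster],
                      period = assign_period(records$date[roster], periods))

  per_sample <- function(def) {
    sub <- filter_records(records, guilds, def$guild, def$species,
                          def$exclude_species)
    if (identical(def$stat, "richness")) {
      sub <- sub[sub$count > 0, , drop = FALSE]
      sub <- sub[!duplicated(paste(sample_key(sub), sub$species)), ,
                 drop = FALSE]
      v <- table(factor(sample_key(sub), levels = levels(frame$key)))
    } else {
      v <- tapply(sub$count, factor(sample_key(sub), levels = levels(frame$key)),
                  sum, default = 0) / intervals
    }
    as.numeric(v[as.character(frame$key)])
  }

  cells <- expand.grid(period = levels(periods$period),
                       site = sort(unique(frame$site)),
                       area = c("nestbox", "control"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(names(defs), function(nm) {
    val <- per_sample(defs[[nm]])
    cellkey <- paste(frame$area, frame$site, frame$period, sep = "|")
    m <- tapply(val, cellkey, mean)
    v <- as.numeric(m[paste(cells$area, cells$site, cells$period, sep = "|")])
    data.frame(response = nm, area = cells$area, site = cells$site,
               period = cells$period, value = v, stringsAsFactors = FALSE)
  }))
  if (anyNA(out$value)) {
    empty <- unique(with(out[is.na(out$value), ],
                         paste(area, site, period, sep = "/")))
    warning("empty design cell(s) recorded as NA: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out$area <- factor(out$area, levels = c("nestbox", "control"))
  out$period <- factor(out$period, levels = levels(periods$period))
  partial <- length(unique(out$site)) < 2 || nlevels(out$period) < 3
  if (partial)
    message("partial design: fewer than 2 sites or 3 periods present")
  structure(out, partial_design = partial,
            class = c("replicate_means", "data.frame"))
}

#' Species x treatment-area sighting table
#'
#' Sums per-interval counts by species and treatment area, in the style of a
#' published sightings table: one row per species with guild, per-area totals
#' and a species total, plus guild subtotals and the grand total. A "sighting"
#' is a summed interval count; the repeated-interval protocol cannot
#' deduplicate individuals.
#'
#' @param records A `pointcount` data frame (may be empty).
#' @param guilds Guild lookup table.
#' @return A `sighting_table`: data frame of species rows with attributes
#'   `guild_totals` (data frame) and `grand_total`.
#' @export
#' @examples
#' pc <- simulate_pointcounts(sim_config(seed = 1))
#' tab <- tabulate_sightings(pc)
#' attr(tab, "grand_total")
tabulate_sightings <- function(records, guilds = vineyard_guilds()) {
  if (nrow(records) == 0) {
    out <- data.frame(species = character(), guild = character(),
                      nestbox = integer(), control = integer(),
                      total = integer(), stringsAsFactors = FALSE)
    gt <- data.frame(guild = character(), nestbox = integer(),
                     control = integer(), total = integer())
    return(structure(out, guild_totals = gt, grand_total = 0L,
                     class = c("sighting_table", "data.frame")))
  }
  g <- as.character(record_guild(records, guilds))
  agg <- tapply(records$count,
                list(records$species, factor(records$area,
                                             c("nestbox", "control"))),
                sum, default = 0L)
  out <- data.frame(species = rownames(agg),
                    guild = as.character(classify_guild(rownames(agg), guilds)),
                    nestbox = as.integer(agg[, "nestbox"]),
                    control = as.integer(agg[, "control"]),
                    stringsAsFactors = FALSE)
  out$total <- out$nestbox + out$control
  out$guild <- factor(out$guild, levels = c("I", "O", "G"))
  out <- out[order(out$guild, -out$total, out$species), ]
  rownames(out) <- NULL
  gt <- aggregate(cbind(nestbox, control, total) ~ guild, data = out, sum)
  structure(out, guild_totals = gt, grand_total = sum(out$total),
            class = c("sighting_table", "data.frame"))
}

#' @export
print.sighting_table <- function(x, ...) {
  print.data.frame(x, ...)
  cat("\nGuild subtotals:\n")
  print.data.frame(attr(x, "guild_totals"), row.names = FALSE)
  cat(sprintf("\nGrand total: %d sightings, %d species\n",
              attr(x, "grand_total"), nrow(x)))
  invisible(x)
}
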