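#' Published sighting totals by species, treatment area and diet guild
#'
#' Species-level totals of bird sightings in the nest-box treatment and
#' control halves of the two study vineyards, with each species assigned to a
#' diet guild: `I` (mostly insectivore), `O` (omnivore) or `G` (granivore).
#' Species are keyed by 4-letter AOU-style codes; Latin and common names are
#' carried for reporting.
#'
#' @return A data frame with columns `species`, `latin_name`, `common_name`,
#'   `guild`, `nestbox`, `control`.
#' @seealso [vineyard_guilds()] for just the species-to-guild lookup,
#'   [tabulate_sightings()] to build the same table from raw records.
#' @export
#' @examples
#' sightings <- vineyard_sightings()
#' sum(sightings$nestbox + sightings$control)  # 1122 birds, 25 species
vineyard_sightings <- function() {
  path <- system.file("extdata", "table1_sightings.csv", package = "vinebirds",
                      mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$guild <- factor(out$guild, levels = c("I", "O", "G"))
  out
}

#' Species-to-guild lookup table
#'
#' @param path Optional path to a guild CSV with columns
#'   `species,latin_name,guild`; defaults to the bundled vineyard species pool.
#' @return A `guild_table`: data frame with columns `species`, `latin_name`,
#'   `guild` (factor with levels I, O, G).
#' @export
#' @examples
#' g <- vineyard_guilds()
#' classify_guild("CHSP", g)
vineyard_guilds <- function(path = NULL) {
  tab <- if (is.null(path)) {
    vineyard_sightings()[, c("species", "latin_name", "guild")]
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  as_guild_table(tab)
}

#' Validate and coerce a data frame to a guild table
#'
#' @param tab Data frame with at least `species` and `guild` columns; `guild`
#'   values must be `I`, `O` or `G`.
#' @return The validated `guild_table`.
#' @export
as_guild_table <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("species", "guild") %in% names(tab)))
  tab$species <- as.character(tab$species)
  tab$guild <- as.character(tab$guild)
  bad <- setdiff(unique(tab$guild), c("I", "O", "G"))
  if (length(bad) > 0)
    stop("unknown guild code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$species))
    stop("duplicated species code(s): ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "),
         call. = FALSE)
  tab$guild <- factor(tab$guild, levels = c("I", "O", "G"))
  if (!"latin_name" %in% names(tab)) tab$latin_name <- NA_character_
  class(tab) <- c("guild_table", "data.frame")
  tab
}

#' Look up the diet guild of a species
#'
#' Resolves a species code (or Latin name) against a guild table. A species
#' absent from the table is an error, never a silent default: guild totals
#' must partition the full species list.
#'
#' @param species Character vector of species codes or Latin names.
#' @param guilds A `guild_table`, by default the bundled vineyard pool.
#' @return Factor of guilds (levels I, O, G), same length as `species`.
#' @export
#' @examples
#' classify_guild(c("Spizella passerina", "Sturnus vulgaris"))
classify_guild <- function(species, guilds = vineyard_guilds()) {
  species <- as.character(species)
  idx <- match(species, guilds$species)
  latin <- match(species, guilds$latin_name)
  idx[is.na(idx)] <- latin[is.na(idx)]
  if (anyNA(idx))
    stop("species not in guild table: ",
         paste(unique(species[is.na(idx)]), collapse = ", "), call. = FALSE)
  guilds$guild[idx]
}

#' Published treatment/control response means
#'
#' The per-treatment means and standard errors of the seven point-count
#' response variables (species richness, insectivore richness, and abundance
#' of all birds, the focal bluebird, non-bluebird insectivores, omnivores and
#' granivores), as printed for the original experiment, together with the
#' reported bootstrap p-values. Used to calibrate the synthetic-data
#' generator's default rates and as worked-example inputs.
#'
#' @return Data frame with columns `response`, `nestbox_mean`, `nestbox_se`,
#'   `control_mean`, `control_se`, `p_printed`.
#' @export
vineyard_response_means <- function() {
  path <- system.file("extdata", "table2_means.csv", package = "vinebirds",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(p_printed = "character"))
}
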