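# Small in-code fixtures shared across test files.

# A hand-written 30-minute sample: three species across two intervals.
tiny_sample <- function() {
  as_pointcounts(data.frame(
    site = "site1", area = "nestbox", point_id = "n1", date = "2009-05-01",
    interval = c(1, 1, 2, 2, 3, 4, 5, 6),
    species = c("WEBL", "CHSP", "WEBL", "HOFI", "WEBL", "WEBL", "WEBL", "WEBL"),
    count = c(2, 1, 3, 1, 1, 2, 2, 2),
    distance_m = c(10, 30, 12, 70, 15, 8, 22, 40)))
}

# Balanced two-group sentinel data with no separation, for closed-form checks.
two_group_sentinel <- function(y1 = c(1, 2, 2, 3, 1, 2),
                               y2 = c(3, 4, 3, 2, 4, 3)) {
  as_sentinel(data.frame(
    site = "site1",
    block = rep(c("b1", "b2"), each = length(y1)),
    group = rep(c("control", "nestbox_random"), each = length(y1)),
    removed = c(y1, y2), n_stations = 5L))
}

# Three-group sentinel fixture spread over four blocks.
three_group_sentinel <- function(seed = 3) {
  simulate_sentinel(sim_config(seed = seed))
}

# Replicate table shaped like the full design (2 sites x 3 periods x 2 areas).
full_replicates <- function(values_trt, values_ctrl, response = "resp") {
  cells <- expand.grid(site = c("site1", "site2"),
                       period = c("early", "middle", "late"),
                       stringsAsFactors = FALSE)
  data.frame(response = response,
             area = rep(c("nestbox", "control"), each = 6),
             site = rep(cells$site, 2), period = rep(cells$period, 2),
             value = c(values_trt, values_ctrl), stringsAsFactors = FALSE)
}

# Records reconstructed from the bundled species x area sighting totals: one
# pseudo-record per species per area carrying the published summed count.
table1_records <- function() {
  sg <- vineyard_sightings()
  long <- rbind(
    data.frame(species = sg$species, area = "nestbox", count = sg$nestbox),
    data.frame(species = sg$species, area = "control", count = sg$control))
  long <- long[long$count > 0, ]
  as_pointcounts(data.frame(
    site = "pooled", area = long$area, point_id = "p1", date = "2009-05-01",
    interval = 1, species = long$species, count = long$count))
}
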