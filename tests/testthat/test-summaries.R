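test_that("richness counts distinct species, optionally by guild", {
  s <- tiny_sample()
  expect_equal(richness(s), 3)                       # WEBL, CHSP, HOFI
  expect_equal(richness(s, guild = "I", guilds = vineyard_guilds()), 2)
  expect_equal(richness(s, guild = "G", guilds = vineyard_guilds()), 1)
  expect_equal(richness(s[0, ]), 0)
  expect_error(richness(s, guild = "I"), "guild table")
  bad <- s; bad$species[1] <- "ZZZZ"
  expect_error(richness(bad, guild = "I", guilds = vineyard_guilds()),
               "not in guild table")
})

test_that("interval abundance is total count over six intervals", {
  s <- tiny_sample()
  s2 <- s[s$species == "WEBL", ]  # counts 2,3,1,2,2,2 across intervals
  expect_equal(interval_abundance(s2), 2.0)
  expect_equal(interval_abundance(s, species = "WEBL"), 2.0)
  expect_equal(interval_abundance(s[0, ]), 0)
  # guild components sum to the total
  g <- vineyard_guilds()
  parts <- sapply(c("I", "O", "G"), function(gg)
    interval_abundance(s, guild = gg, guilds = g))
  expect_equal(sum(parts), interval_abundance(s))
  # excluding the focal species removes exactly its share
  expect_equal(interval_abundance(s, guild = "I", guilds = g,
                                  exclude_species = "WEBL") +
                 interval_abundance(s, species = "WEBL"),
               interval_abundance(s, guild = "I", guilds = g))
})

test_that("replicate means average per-sample statistics within cells", {
  # two samples in one cell with per-sample values 1.0 and 3.0 -> mean 2.0
  rec <- as_pointcounts(data.frame(
    site = "site1", area = rep(c("nestbox", "control"), each = 12),
    point_id = rep(c("p1", "p2", "c1", "c2"), each = 6),
    date = "2009-05-01", interval = rep(1:6, 4), species = "WEBL",
    count = c(rep(1, 6), rep(3, 6), rep(1, 12))))
  rm1 <- suppressWarnings(suppressMessages(
    replicate_means(rec, "bluebird_abundance", periods = season_periods())))
  expect_equal(rm1$value[rm1$area == "nestbox" & rm1$period == "early"], 2.0)
  expect_true(attr(rm1, "partial_design"))  # single site
  expect_equal(sum(rm1$area == "nestbox" & !is.na(rm1$value)), 1)

  # full synthetic design: 6 replicates per treatment per response
  pc <- simulate_pointcounts(sim_config(seed = 21))
  rm6 <- replicate_means(pc, c("total_abundance", "richness"))
  expect_false(attr(rm6, "partial_design"))
  for (resp in unique(rm6$response)) {
    sub <- rm6[rm6$response == resp, ]
    expect_equal(sum(sub$area == "nestbox"), 6)
    expect_equal(sum(sub$area == "control"), 6)
    expect_false(anyNA(sub$value))
  }
})

test_that("summaries are invariant to record order", {
  pc <- simulate_pointcounts(sim_config(seed = 31))
  perm <- withr::with_seed(1, sample(nrow(pc)))
  shuffled <- as_pointcounts(as.data.frame(pc)[perm, ])
  a <- replicate_means(pc, "insectivore_richness")
  b <- replicate_means(shuffled, "insectivore_richness")
  expect_equal(as.data.frame(a[order(a$area, a$site, a$period), ]),
               as.data.frame(b[order(b$area, b$site, b$period), ]),
               ignore_attr = TRUE)
  ta <- tabulate_sightings(pc)
  tb <- tabulate_sightings(shuffled)
  expect_equal(as.data.frame(ta), as.data.frame(tb))
})

test_that("guild abundances add up to the total abundance", {
  pc <- simulate_pointcounts(sim_config(seed = 41))
  rm6 <- replicate_means(pc)
  tot <- rm6$value[rm6$response == "total_abundance"]
  parts <- rm6$value[rm6$response == "bluebird_abundance"] +
    rm6$value[rm6$response == "nonbluebird_insectivore_abundance"] +
    rm6$value[rm6$response == "omnivore_abundance"] +
    rm6$value[rm6$response == "granivore_abundance"]
  expect_equal(parts, tot)
  # richness never exceeds the species pool actually seen
  r <- rm6$value[rm6$response == "richness"]
  expect_true(all(r <= length(unique(pc$species))))
})

test_that("sighting tabulation reproduces published totals when re-entered", {
  tab <- tabulate_sightings(table1_records())
  expect_equal(attr(tab, "grand_total"), 1122)
  expect_equal(nrow(tab), 25)
  gt <- attr(tab, "guild_totals")
  expect_equal(gt$nestbox[gt$guild == "I"], 455)   # column-sum oracle
  expect_equal(sum(gt$total), 1122)
  expect_equal(tab$total[tab$species == "WEBL"], 313 + 39)

  # empty input gives an empty table with zero totals
  empty <- tabulate_sightings(table1_records()[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "grand_total"), 0)
})
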