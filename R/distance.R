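#' Distance-from-nest profiles of focal-species detections
#'
#' Bins detection distances of the focal species (in the nest-box half, where
#' observation points sit at active nests) into distance classes per
#' breeding-season period. Default bins are 0-20, 21-42, 43-64 and 65-85 m;
#' the last bin is the far field, detections more than 64 m from an active
#' nest. Records without a distance (heard-only) are excluded and their count
#' reported.
#'
#' @param records A `pointcount` data frame.
#' @param species Focal species code (default `"WEBL"`).
#' @param area Treatment half to profile (default `"nestbox"`).
#' @param breaks Upper bin edges in meters, ending at the observation radius
#'   (default `c(20, 42, 64, 85)`); bins are inclusive of their upper edge.
#' @param periods A [season_periods()] table.
#' @param weight_by_count Count each record `count` times (default `TRUE`).
#' @return A `distance_profile` data frame with columns `period`, `bin`,
#'   `lower`, `upper`, `count`, `proportion` (NA when a period has no
#'   detections), plus attributes `n_excluded` (records without distance),
#'   `n_by_period` and `far_field` (per-period proportion in the last bin).
#' @export
#' @examples
#' pc <- simulate_pointcounts(sim_config(seed = 1))
#' distance_profile(pc)
distance_profile <- function(records, species = "WEBL", area = "nestbox",
                             breaks = c(20, 42, 64, 85),
                             periods = season_periods(),
                             weight_by_count = TRUE) {
  stopifnot(length(breaks) >= 1, !is.unsorted(breaks))
  sub <- records[records$species == species &
                   as.character(records$area) == area, , drop = FALSE]
  n_excluded <- sum(is.na(sub$distance_m))
  sub <- sub[!is.na(sub$distance_m), , drop = FALSE]
  if (any(sub$distance_m > breaks[length(breaks)]))
    stop("bins must cover all recorded distances", call. = FALSE)

  lower <- c(0, breaks[-length(breaks)] + 1)
  labels <- sprintf("%g-%g", lower, breaks)
  bin <- factor(labels[findInterval(sub$distance_m,
                                    c(0, breaks[-length(breaks)] + 0.5)) ],
                levels = labels)
  period <- assign_period(sub$date, periods)
  w <- if (weight_by_count) sub$count else rep(1L, nrow(sub))

  counts <- tapply(w, list(period, bin), sum, default = 0L)
  counts <- counts[levels(periods$period), labels, drop = FALSE]
  n_by_period <- rowSums(counts)
  prop <- sweep(counts, 1, n_by_period, "/")  # NaN where n = 0

  out <- data.frame(
    period = factor(rep(rownames(counts), times = ncol(counts)),
                    levels = levels(periods$period)),
    bin = factor(rep(labels, each = nrow(counts)), levels = labels),
    lower = rep(lower, each = nrow(counts)),
    upper = rep(breaks, each = nrow(counts)),
    count = as.vector(counts),
    proportion = ifelse(is.nan(as.vector(prop)), NA_real_, as.vector(prop)))
  out <- out[order(out$period, out$lower), ]
  rownames(out) <- NULL
  if (any(n_by_period == 0))
    warning("period(s) with no detections: ",
            paste(names(n_by_period)[n_by_period == 0], collapse = ", "),
            call. = FALSE)
  structure(out, n_excluded = n_excluded, n_by_period = n_by_period,
            far_field = prop[, ncol(prop)],
            class = c("distance_profile", "data.frame"))
}

#' Bar chart of a distance profile
#'
#' Grouped bars of detection proportions by distance class within each period,
#' drawn with base graphics.
#'
#' @param x A [distance_profile()] result.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.distance_profile <- function(x, ...) {
  m <- tapply(x$proportion, list(x$bin, x$period), identity)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    xlab = "Breeding-season period",
                    ylab = "Proportion of detections",
                    args.legend = list(title = "Distance from nest (m)",
                                       x = "topright", bty = "n"), ...)
  invisible(x)
}

#' Bar chart of sentinel removal means by group
#'
#' Group means (+/- SE) of larvae removed out of five, drawn with base
#' graphics.
#'
#' @param transects A `sentinel` data frame.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the data frame of group means and SEs.
#' @export
plot_removal_means <- function(transects, ...) {
  transects <- as_sentinel(as.data.frame(transects))
  mns <- tapply(transects$removed, transects$group, mean)
  ses <- tapply(transects$removed, transects$group,
                function(v) stats::sd(v) / sqrt(length(v)))
  bp <- graphics::barplot(mns, ylim = c(0, 5), ylab = "Larvae removed (of 5)",
                          ...)
  graphics::arrows(bp, mns - ses, bp, mns + ses, angle = 90, code = 3,
                   length = 0.06)
  invisible(data.frame(group = names(mns), mean = as.numeric(mns),
                       se = as.numeric(ses),
                       n = as.integer(table(transects$group))))
}
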