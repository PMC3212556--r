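#' Pooled-bootstrap null distribution of treatment-mean differences
#'
#' Under the null hypothesis of no treatment effect the replicate means of the
#' two treatments are exchangeable, so both groups are pooled and two
#' independent sets of `B` bootstrap means (each the mean of `m` draws with
#' replacement from the pool) are generated; their elementwise difference is
#' the null distribution of the difference between two treatment means of
#' size `m`.
#'
#' @param trt,ctrl Numeric replicate means for the two treatments (typically
#'   6 each: 2 sites x 3 periods).
#' @param B Number of bootstrap differences (default 1000).
#' @param m Resample size per mean (default 6, the replicate count).
#' @param seed Seed for the resampling stream (`NULL` = current RNG state).
#' @return Numeric vector of `B` null differences.
#' @export
#' @examples
#' pooled_bootstrap_null(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7), B = 10,
#'                       seed = 1)
pooled_bootstrap_null <- function(trt, ctrl, B = 1000, m = 6, seed = NULL) {
  trt <- as.numeric(trt); ctrl <- as.numeric(ctrl)
  if (length(trt) == 0 || length(ctrl) == 0)
    stop("both treatment groups must be non-empty", call. = FALSE)
  if (anyNA(trt) || anyNA(ctrl))
    stop("replicate means contain NA (incomplete design)", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pool <- sort(c(trt, ctrl))  # label-order invariant: swapping groups
                              # reproduces the same null under the same seed
  with_seed(seed, {
    m1 <- rowMeans(matrix(sample(pool, B * m, replace = TRUE), nrow = B))
    m2 <- rowMeans(matrix(sample(pool, B * m, replace = TRUE), nrow = B))
    m1 - m2
  })
}

#' Empirical p-value of an observed difference against a null distribution
#'
#' Uses the add-one rule `p = (1 + r) / (B + 1)` where `r` counts null values
#' at least as extreme as the observation (ties count as exceedances), so `p`
#' is never 0 and is always a multiple of `1/(B+1)`. Two-sided compares
#' absolute values; one-sided compares signed values (greater).
#'
#' @param observed Observed difference (nest-box mean minus control mean).
#' @param null_diffs Null differences from [pooled_bootstrap_null()].
#' @param sided `"two_sided"` (default) or `"one_sided_greater"`.
#' @return Empirical p-value in `(0, 1]`.
#' @export
#' @examples
#' empirical_p(2, c(-1, 0, 1, 3))  # (1 + 1) / (4 + 1) = 0.4
empirical_p <- function(observed, null_diffs,
                        sided = c("two_sided", "one_sided_greater")) {
  sided <- match.arg(sided)
  if (length(null_diffs) == 0) stop("empty null distribution", call. = FALSE)
  r <- if (sided == "two_sided") {
    sum(abs(null_diffs) >= abs(observed))
  } else {
    sum(null_diffs >= observed)
  }
  (1 + r) / (length(null_diffs) + 1)
}

#' Bootstrap treatment tests across all response variables
#'
#' Runs the pooled-bootstrap null test for each requested response on a
#' replicate-mean table. Each response draws from its own RNG substream,
#' derived from the master seed and the response name, so adding or reordering
#' responses never perturbs the others.
#'
#' @param replicates A [replicate_means()] table (or data frame with columns
#'   `response`, `area`, `site`, `period`, `value`).
#' @param responses Responses to test; default all present in `replicates`.
#' @param B,m,sided As in [pooled_bootstrap_null()] / [empirical_p()].
#' @param seed Master seed (mandatory).
#' @return Data frame (class `boot_suite`) with one row per response:
#'   `response`, `nestbox_mean`, `control_mean`, `observed_diff`, `p_value`,
#'   `B`, `m`, `sided`, `seed`; attribute `null_diffs` holds the named list of
#'   null vectors.
#' @export
#' @examples
#' pc <- simulate_pointcounts(sim_config(seed = 1))
#' rm6 <- replicate_means(pc, c("bluebird_abundance", "omnivore_abundance"))
#' run_bootstrap_suite(rm6, B = 199, seed = 7)
run_bootstrap_suite <- function(replicates, responses = NULL, B = 1000, m = 6,
                                sided = "two_sided", seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  responses <- responses %||% unique(replicates$response)
  rows <- list(); nulls <- list()
  for (resp in responses) {
    sub <- replicates[replicates$response == resp, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("response not in replicate table: ", resp, call. = FALSE)
    cells <- expand.grid(area = c("nestbox", "control"),
                         site = unique(sub$site),
                         period = unique(as.character(sub$period)),
                         stringsAsFactors = FALSE)
    have <- paste(sub$area[!is.na(sub$value)], sub$site[!is.na(sub$value)],
                  as.character(sub$period)[!is.na(sub$value)])
    missing_cells <- setdiff(paste(cells$area, cells$site, cells$period), have)
    if (length(missing_cells) > 0)
      stop("incomplete design for '", resp, "'; missing cell(s): ",
           paste(missing_cells, collapse = ", "), call. = FALSE)
    trt <- sub$value[sub$area == "nestbox"]
    ctrl <- sub$value[sub$area == "control"]
    obs <- mean(trt) - mean(ctrl)
    nd <- pooled_bootstrap_null(trt, ctrl, B = B, m = m,
                                seed = derive_seed(seed, resp))
    nulls[[resp]] <- nd
    rows[[resp]] <- data.frame(
      response = resp, nestbox_mean = mean(trt), control_mean = mean(ctrl),
      nestbox_se = stats::sd(trt) / sqrt(length(trt)),
      control_se = stats::sd(ctrl) / sqrt(length(ctrl)),
      observed_diff = obs, p_value = empirical_p(obs, nd, sided),
      B = B, m = m, sided = sided, seed = seed, stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            null_diffs = nulls, class = c("boot_suite", "data.frame"))
}

#' @export
print.boot_suite <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$p_value <- ifelse(y$p_value < 1 / (y$B + 1) + 1e-12,
                      sprintf("<%.3g", 1 / y$B), format(round(y$p_value, 4)))
  print.data.frame(y[, c("response", "nestbox_mean", "control_mean",
                         "observed_diff", "p_value")], digits = digits,
                   row.names = FALSE)
  invisible(x)
}
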