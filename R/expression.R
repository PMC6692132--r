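#' Process plate-reader reporter time series into relative expression
#'
#' Converts optical-density and fluorescence time series into one
#' maximum relative expression value per strain, wild type = 1. For each
#' strain the background strain's fluorescence is subtracted at every time
#' point, the time of maximum net signal is located, the net signal there
#' is standardised by the blank-corrected optical density at the same time,
#' and the result is divided by the wild-type value. The maximum is taken
#' over the whole series rather than at a fixed time. Records whose
#' blank-corrected OD at the chosen time is non-positive are rejected with
#' a reason. The value is invariant to a common rescaling of all
#' fluorescence signals, and to a common rescaling of blank-corrected OD.
#'
#' @param timeseries long-format data.frame with columns `strain`, `time`,
#'   `od`, `fluorescence`; replicate rows per (strain, time) are averaged.
#' @param background_strain strain id providing background fluorescence
#'   (an unmarked, reporter-free strain).
#' @param blank_wells strain id of the media-only blank wells (OD baseline).
#' @param wt_strain strain id of the reporter-carrying wild type.
#' @return data.frame with `strain`, `max_relative_expression`, `t_max`,
#'   `rejected`, `reason`.
#' @export
process_expression <- function(timeseries, background_strain, blank_wells,
                               wt_strain) {
  need <- c("strain", "time", "od", "fluorescence")
  stopifnot(all(need %in% names(timeseries)))
  agg <- aggregate(cbind(od, fluorescence) ~ strain + time,
                   data = timeseries, FUN = mean)
  times <- sort(unique(agg$time))
  series <- function(id, col) {
    s <- agg[agg$strain == id, ]
    if (nrow(s) == 0) stop("strain not found in time series: ", id)
    s <- s[match(times, s$time), ]
    if (any(is.na(s$time))) stop("strain ", id, " missing time points")
    s[[col]]
  }
  f_bg <- series(background_strain, "fluorescence")
  od_blank <- series(blank_wells, "od")

  raw_value <- function(id) {
    f_net <- series(id, "fluorescence") - f_bg
    t_idx <- which.max(f_net)
    denom <- series(id, "od")[t_idx] - od_blank[t_idx]
    if (denom <= 0)
      return(list(value = NA_real_, t = times[t_idx],
                  reason = "blank-corrected OD <= 0 at max-signal time"))
    list(value = f_net[t_idx] / denom, t = times[t_idx], reason = NA_character_)
  }

  wt <- raw_value(wt_strain)
  if (is.na(wt$value)) stop("wild-type record rejected: ", wt$reason)
  strains <- setdiff(unique(agg$strain), c(background_strain, blank_wells))
  out <- do.call(rbind, lapply(strains, function(id) {
    r <- raw_value(id)
    data.frame(strain = id,
               max_relative_expression = r$value / wt$value,
               t_max = r$t, rejected = is.na(r$value),
               reason = r$reason, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Regression of fitness on relative transcript-reporter expression
#'
#' Joins fitness estimates with relative expression values on
#' `mutation_id`, restricts to synonymous mutations (when a `class` column
#' is present), and fits fitness on expression by OLS with
#' permutation-of-residuals inference via [permlm()], reporting the
#' adjusted R-squared.
#'
#' @param fitness data.frame with `mutation_id`, `w_mean` (or `w`), and
#'   optionally `class`.
#' @param expression data.frame with `mutation_id` and
#'   `relative_expression` (or `max_relative_expression`).
#' @param synonymous_only restrict to synonymous mutations when class
#'   information is available.
#' @param B,seed passed to [permlm()].
#' @return a [permlm()] object (attribute `n_joined` records the join size).
#' @export
expression_fitness_regression <- function(fitness, expression,
                                          synonymous_only = TRUE,
                                          B = 10000, seed = NULL) {
  wcol <- if ("w_mean" %in% names(fitness)) "w_mean" else "w"
  ecol <- if ("relative_expression" %in% names(expression))
    "relative_expression" else "max_relative_expression"
  d <- merge(fitness, expression, by = "mutation_id")
  if (synonymous_only && "class" %in% names(d))
    d <- d[d$class == "synonymous", , drop = FALSE]
  if (nrow(d) < 3)
    stop("join produced fewer than 3 rows: cannot regress")
  d2 <- data.frame(fitness = d[[wcol]], expression = d[[ecol]])
  res <- permlm(fitness ~ expression, d2, B = B, seed = seed)
  attr(res, "n_joined") <- nrow(d2)
  res
}
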