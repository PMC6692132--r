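#' Relative fitness of one competition replicate
#'
#' Relative fitness per doubling from a head-to-head competition against a
#' marked reference strain: `w = (f_final / f_initial)^(1 / doublings)`,
#' where `f` is the ratio of mutant to reference frequency (equivalently,
#' the mutant:reference count ratio on a plate). Swapping the mutant and
#' reference labels maps `w` to `1/w`.
#'
#' @param mutant_initial,ref_initial,mutant_final,ref_final colony counts;
#'   fractional counts are accepted (noiseless expected counts invert the
#'   formula exactly).
#' @param doublings number of population doublings over the competition
#'   (commonly about 6.7 or 13.2 depending on dilution; see
#'   [doubling_presets]).
#' @return relative fitness `w > 0`.
#' @examples
#' replicate_fitness(60, 40, 80, 20, doublings = 6.7)
#' @export
replicate_fitness <- function(mutant_initial, ref_initial,
                              mutant_final, ref_final, doublings) {
  stopifnot(doublings > 0)
  if (any(c(mutant_initial, ref_initial, mutant_final, ref_final) <= 0))
    stop("all four counts must be > 0 to compute a finite fitness")
  f_init <- mutant_initial / ref_initial
  f_final <- mutant_final / ref_final
  (f_final / f_init)^(1 / doublings)
}

#' Named presets for the number of doublings
#'
#' Typical doubling numbers implied by the two dilution regimes of a 24 h
#' serial competition assay.
#' @format named numeric vector with elements `low_dilution` (6.7) and
#'   `high_dilution` (13.2).
#' @export
doubling_presets <- c(low_dilution = 6.7, high_dilution = 13.2)

# Apply inclusion filters to a competition count table; returns the table
# with `included` and `exclusion_reason` columns added.
filter_replicates <- function(counts, min_colonies = 30) {
  reason <- rep(NA_character_, nrow(counts))
  zero <- with(counts, mutant_initial <= 0 | ref_initial <= 0 |
                 mutant_final <= 0 | ref_final <= 0)
  reason[zero] <- "zero colony count"
  low <- with(counts, pmin(mutant_initial, ref_initial,
                           mutant_final, ref_final) < min_colonies)
  reason[low & is.na(reason)] <-
    sprintf("fewer than %d colonies of a strain on a plate", min_colonies)
  counts$included <- is.na(reason)
  counts$exclusion_reason <- reason
  counts
}

#' Estimate per-mutation fitness from a competition count table
#'
#' Applies the plate-inclusion filter (every plate must carry at least
#' `min_colonies` colonies of each strain; zero counts are always
#' excluded), computes per-replicate fitness with [replicate_fitness()],
#' and aggregates per mutation as the arithmetic mean with its standard
#' error (`sd/sqrt(n)`; NA for a single replicate). Mutations whose
#' replicates are all excluded are flagged, not silently dropped. Mutations
#' with fewer than four surviving replicates trigger a warning, reflecting
#' the assay's usual four-to-six technical replicates.
#'
#' @param counts data.frame with columns `mutation_id`, `replicate`,
#'   `mutant_initial`, `ref_initial`, `mutant_final`, `ref_final`,
#'   `doublings` (e.g. read from `competitions.csv`).
#' @param min_colonies plate-inclusion threshold.
#' @param marker_correction optional control fitness estimate (from
#'   [marker_control()]); when supplied, every mutant `w` is divided by the
#'   control mean. No correction is applied by default.
#' @return object of class `"fitness_table"`: a data.frame with
#'   `mutation_id`, `w_mean`, `sem`, `n_replicates`, `n_excluded`, plus
#'   attributes `replicates` (per-replicate w) and `excluded` (exclusion
#'   log).
#' @export
estimate_fitness <- function(counts, min_colonies = 30,
                             marker_correction = NULL) {
  need <- c("mutation_id", "mutant_initial", "ref_initial",
            "mutant_final", "ref_final", "doublings")
  if (!all(need %in% names(counts)))
    stop("missing columns: ", paste(setdiff(need, names(counts)), collapse = ", "))
  counts <- filter_replicates(counts, min_colonies)
  inc <- counts[counts$included, , drop = FALSE]
  inc$w <- with(inc, replicate_fitness(mutant_initial, ref_initial,
                                       mutant_final, ref_final, doublings))
  correction <- 1
  if (!is.null(marker_correction)) {
    correction <- if (is.list(marker_correction)) marker_correction$w_mean
                  else as.numeric(marker_correction)
    inc$w <- inc$w / correction
  }

  ids <- unique(counts$mutation_id)
  agg <- do.call(rbind, lapply(ids, function(id) {
    w <- inc$w[inc$mutation_id == id]
    n_exc <- sum(counts$mutation_id == id) - length(w)
    if (length(w) == 0)
      return(data.frame(mutation_id = id, w_mean = NA_real_, sem = NA_real_,
                        n_replicates = 0L, n_excluded = n_exc,
                        stringsAsFactors = FALSE))
    data.frame(mutation_id = id, w_mean = mean(w),
               sem = if (length(w) > 1) sd(w) / sqrt(length(w)) else NA_real_,
               n_replicates = length(w), n_excluded = n_exc,
               stringsAsFactors = FALSE)
  }))
  n_missing <- sum(agg$n_replicates == 0)
  if (n_missing > 0)
    warning(n_missing, " mutation(s) have no surviving replicates ",
            "and carry NA fitness")
  n_thin <- sum(agg$n_replicates > 0 & agg$n_replicates < 4)
  if (n_thin > 0)
    warning(n_thin, " mutation(s) estimated from fewer than 4 replicates")
  structure(agg,
            replicates = inc[, c("mutation_id", "w")],
            excluded = counts[!counts$included,
                              c("mutation_id", "exclusion_reason")],
            marker_correction = correction,
            class = c("fitness_table", "data.frame"))
}

#' Marker-control fitness estimate
#'
#' The same estimator as [estimate_fitness()] applied to competitions of
#' the marked reference strain against the unmarked wild type, summarised
#' as a single control estimate (`w_mean`, `sem`, `n`). An empty control
#' table yields a warning and a NULL (no correction available).
#'
#' @inheritParams estimate_fitness
#' @return list with `w_mean`, `sem`, `n_replicates`, or NULL for an empty
#'   control set.
#' @export
marker_control <- function(counts, min_colonies = 30) {
  if (is.null(counts) || nrow(counts) == 0) {
    warning("empty marker-control set: no correction applied")
    return(NULL)
  }
  counts$mutation_id <- "marker_control"
  ft <- suppressWarnings(estimate_fitness(counts, min_colonies))
  list(w_mean = ft$w_mean[1], sem = ft$sem[1],
       n_replicates = ft$n_replicates[1])
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("Fitness estimates for", nrow(x), "mutations",
      sprintf("(marker correction %.4g)\n", attr(x, "marker_correction")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
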