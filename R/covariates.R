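#' Codon-level covariate changes for a point mutation
#'
#' Computes the change in gene-level CAI (and tAI, when a tRNA table is
#' supplied) caused by a single substitution, together with the codon index
#' and the nucleotide distance from the start codon
#' (`cds_position - 1`; a mutation in the first base of codon 1 is at
#' distance 0). Deltas are mutant minus reference. Nonsense mutations are
#' rejected, since the truncated protein has no complete-gene metric.
#'
#' @inheritParams apply_mutation
#' @param usage a [codon_usage_table()].
#' @param trna optional [trna_copy_table()].
#' @return list with `delta_cai`, `delta_tai` (NA without `trna`),
#'   `codon_index`, `distance_from_start_nt`, `class`.
#' @export
delta_metrics <- function(cds, mut, usage, trna = NULL) {
  cls <- classify_mutation(cds, mut)
  if (cls == "nonsense")
    stop("delta metrics undefined for nonsense mutations (no complete protein)")
  mut_cds <- apply_mutation(cds, mut)
  dcai <- compute_cai(mut_cds, usage)$cai - compute_cai(cds, usage)$cai
  dtai <- if (is.null(trna)) NA_real_ else
    compute_tai(mut_cds, trna)$tai - compute_tai(cds, trna)$tai
  list(delta_cai = dcai, delta_tai = dtai,
       codon_index = mut$codon_index,
       distance_from_start_nt = mut$cds_position - 1L,
       class = cls)
}

#' Extract the mRNA window centred on a mutation
#'
#' Returns the reference and mutant sequence of a fixed-width window centred
#' on the mutated base, for downstream folding-energy prediction by an
#' external tool. For an even width `W` the window spans CDS positions
#' `[p - W/2, p + W/2 - 1]`, placing the mutated base immediately right of
#' centre (0-based offset `W/2` within the window). Flanking sequence
#' stored on the `coding_sequence` is used beyond the CDS ends; if the
#' window still runs off the available sequence it is truncated and
#' flagged.
#'
#' @inheritParams apply_mutation
#' @param width window width in nucleotides (even).
#' @return list with `ref_window`, `mut_window`, `start`, `end` (CDS
#'   coordinates; may extend into flanks as values `< 1` or `> nchar(cds)`),
#'   `mut_offset` (0-based index of the mutated base within the window) and
#'   `truncated`.
#' @export
extract_mrna_window <- function(cds, mut, width = 42) {
  stopifnot(width %% 2 == 0, width >= 2)
  check_mutation(cds, mut)
  half <- width %/% 2
  full <- paste0(cds$flank5, cds$nucleotides, cds$flank3)
  off5 <- nchar(cds$flank5)
  p_full <- off5 + mut$cds_position
  lo <- p_full - half
  hi <- p_full + half - 1L
  lo_c <- max(lo, 1L)
  hi_c <- min(hi, nchar(full))
  truncated <- (lo_c != lo) || (hi_c != hi)
  ref_window <- substr(full, lo_c, hi_c)
  mut_window <- ref_window
  pos_in_window <- p_full - lo_c + 1L
  substr(mut_window, pos_in_window, pos_in_window) <- mut$alt_base
  list(ref_window = ref_window, mut_window = mut_window,
       start = lo_c - off5, end = hi_c - off5,
       mut_offset = pos_in_window - 1L, truncated = truncated)
}

#' Per-mutation covariate table
#'
#' Applies [delta_metrics()] across a mutation list, skipping nonsense
#' mutations (reported), and optionally joins an externally computed
#' folding-energy change column (`delta_mfe` keyed by `mutation_id`) --
#' folding energies themselves are inputs from an external predictor, not
#' computed here.
#'
#' @param cds a [coding_sequence()].
#' @param mutations data.frame with columns `mutation_id`, `cds_position`,
#'   `ref_base`, `alt_base`.
#' @param usage a [codon_usage_table()].
#' @param trna optional [trna_copy_table()].
#' @param mfe optional data.frame with `mutation_id`, `delta_mfe`.
#' @return data.frame with one row per non-nonsense mutation.
#' @export
mutation_covariates <- function(cds, mutations, usage, trna = NULL, mfe = NULL) {
  rows <- lapply(seq_len(nrow(mutations)), function(i) {
    m <- mutations[i, ]
    mut <- point_mutation(m$cds_position, m$ref_base, m$alt_base)
    cls <- classify_mutation(cds, mut)
    if (cls == "nonsense") return(NULL)
    d <- delta_metrics(cds, mut, usage, trna)
    data.frame(mutation_id = m$mutation_id, class = cls,
               delta_cai = d$delta_cai, delta_tai = d$delta_tai,
               codon_index = d$codon_index,
               distance_from_start_nt = d$distance_from_start_nt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_skipped <- nrow(mutations) - nrow(out)
  if (n_skipped > 0)
    message(n_skipped, " nonsense mutation(s) skipped in covariate table")
  if (!is.null(mfe))
    out <- merge(out, mfe[, c("mutation_id", "delta_mfe")],
                 by = "mutation_id", all.x = TRUE, sort = FALSE)
  out
}

#' Test for a translational ramp of rare codons near the gene start
#'
#' Examines whether codon adaptiveness is depressed in the early part of
#' the gene: (a) a linear trend of per-codon weight on codon index along
#' the whole gene and (b) a contrast of the first `first_n` codons against
#' the remainder. Both use the permutation engine of [permlm()] for
#' inference. Weights come from the CAI usage table by default, or from
#' tAI weights if a tRNA table is supplied instead.
#'
#' @param cds a [coding_sequence()].
#' @param usage a [codon_usage_table()], or NULL if `trna` is given.
#' @param trna optional [trna_copy_table()]; used when `usage` is NULL.
#' @param first_n length of the putative ramp in codons.
#' @param B permutations.
#' @param seed RNG seed.
#' @return object of class `"ramp_test"`: `trend` ([permlm()] of weight on
#'   index), `contrast` ([permlm()] on the early-gene indicator, or NULL
#'   with a warning for genes shorter than `first_n + 2` codons), and the
#'   per-codon `weights` table.
#' @export
ramp_test <- function(cds, usage = NULL, trna = NULL, first_n = 50,
                      B = 10000, seed = NULL) {
  if (is.null(usage) && is.null(trna))
    stop("supply a codon usage table or a tRNA copy table")
  if (!is.null(usage)) {
    cw <- compute_cai(cds, usage)$codon_weights
  } else {
    cw <- compute_tai(cds, trna)$codon_weights
  }
  d <- data.frame(index = seq_along(cw), weight = as.numeric(cw))
  trend <- permlm(weight ~ index, d, B = B, seed = seed)
  contrast <- NULL
  if (nrow(d) >= first_n + 2) {
    d$early <- as.numeric(d$index <= first_n)
    contrast <- permlm(weight ~ early, d, B = B, seed = seed)
  } else {
    warning("gene shorter than ", first_n + 2,
            " scored codons: first-", first_n, " contrast skipped")
  }
  structure(list(trend = trend, contrast = contrast, weights = d,
                 first_n = first_n),
            class = "ramp_test")
}

#' @export
print.ramp_test <- function(x, ...) {
  cat("Rare-codon ramp test\n")
  cat(sprintf("  trend (weight ~ index): slope = %.4g, adj R2 = %.4f, p = %.4g\n",
              x$trend$coefficients[["index"]], x$trend$adj_r_squared,
              x$trend$p_perm[["index"]]))
  if (!is.null(x$contrast))
    cat(sprintf("  first-%d contrast: effect = %.4g, p = %.4g\n", x$first_n,
                x$contrast$coefficients[["early"]],
                x$contrast$p_perm[["early"]]))
  invisible(x)
}
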