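#' Build class-wise distributions of fitness effects
#'
#' Splits a fitness table (with mutation classes) into the synonymous and
#' nonsynonymous DFE samples. Nonsense mutations can either be merged into
#' the nonsynonymous sample (they are nonsynonymous changes in the wide
#' sense, and their strongly deleterious effects are part of the full-DFE
#' comparison) or dropped entirely, as is done for tail and covariate
#' analyses where a truncated protein is uninformative.
#'
#' @param fitness data.frame with columns `mutation_id`, `class`
#'   (`synonymous` / `nonsynonymous` / `nonsense`) and `w_mean` (or `w`).
#' @param include_nonsense merge nonsense rows into the nonsynonymous
#'   sample (TRUE) or drop them (FALSE).
#' @return list with data.frames `synonymous` and `nonsynonymous`, each
#'   carrying `mutation_id`, `class`, `w` and `s = w - 1`.
#' @export
build_dfe <- function(fitness, include_nonsense = TRUE) {
  wcol <- if ("w_mean" %in% names(fitness)) "w_mean" else "w"
  stopifnot(all(c("mutation_id", "class") %in% names(fitness)),
            wcol %in% names(fitness))
  f <- fitness[!is.na(fitness[[wcol]]), , drop = FALSE]
  if (any(f[[wcol]] <= 0)) stop("fitness values must be > 0")
  mk <- function(rows) {
    data.frame(mutation_id = rows$mutation_id, class = rows$class,
               w = rows[[wcol]], s = rows[[wcol]] - 1,
               stringsAsFactors = FALSE)
  }
  syn <- mk(f[f$class == "synonymous", ])
  nsyn_classes <- if (include_nonsense) c("nonsynonymous", "nonsense")
                  else "nonsynonymous"
  nsyn <- mk(f[f$class %in% nsyn_classes, ])
  if (nrow(syn) == 0 || nrow(nsyn) == 0)
    stop("empty class sample: check the class column")
  list(synonymous = syn, nonsynonymous = nsyn)
}

# Two-sample Kolmogorov-Smirnov statistic, fast path (no p-value).
ks_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  o <- order(pooled)
  grp <- rep(c(1 / na, -1 / nb), c(na, nb))[o]
  d <- cumsum(grp)
  # with ties, evaluate the ECDF difference only after the last tied value
  z <- pooled[o]
  last_of_run <- c(z[-1] != z[-length(z)], TRUE)
  max(abs(d[last_of_run]))
}

#' Permutation-bootstrapped two-sample Kolmogorov-Smirnov test
#'
#' The observed statistic `D` is the supremum distance between the two
#' empirical CDFs. Its null distribution is built by resampling under
#' exchangeability: the samples are pooled and class labels reshuffled `B`
#' times (default), recomputing `D*` each time, with
#' `p = (1 + #\{D* >= D\}) / (B + 1)`. A resample-with-replacement variant
#' (`method = "bootstrap"`: each pseudo-sample drawn from the pooled values
#' with replacement) is provided as an alternative reading of
#' "bootstrapping the K-S statistic". The test is symmetric in its
#' arguments at a fixed seed.
#'
#' @param sample_a,sample_b numeric vectors (e.g. selection coefficients).
#' @param B number of resamples.
#' @param seed RNG seed (NULL = current stream).
#' @param method `"permutation"` (pooled label shuffle) or `"bootstrap"`.
#' @return object of class `"ks_permutation"`: `D`, `p`, `B`, `seed`,
#'   `method`, `n_a`, `n_b`.
#' @examples
#' ks_compare(rnorm(30), rnorm(40), B = 199, seed = 1)
#' @export
ks_compare <- function(sample_a, sample_b, B = 10000, seed = NULL,
                       method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  stopifnot(B >= 1, length(sample_a) >= 1, length(sample_b) >= 1,
            all(is.finite(sample_a)), all(is.finite(sample_b)))
  # canonical argument order so that swapping the samples leaves the
  # resampling stream, and hence D and p, exactly unchanged
  swap <- length(sample_b) < length(sample_a)
  if (length(sample_b) == length(sample_a)) {
    sa <- sort(sample_a); sb <- sort(sample_b)
    d <- which(sa != sb)
    if (length(d) > 0) swap <- sb[d[1]] < sa[d[1]]
  }
  if (swap) { tmp <- sample_a; sample_a <- sample_b; sample_b <- tmp }
  na <- length(sample_a); nb <- length(sample_b)
  D <- ks_statistic(sample_a, sample_b)
  pooled <- c(sample_a, sample_b)
  n <- na + nb
  Dstar <- with_seed(seed, vapply(seq_len(B), function(i) {
    if (method == "permutation") {
      idx <- sample.int(n, na)
      ks_statistic(pooled[idx], pooled[-idx])
    } else {
      ks_statistic(sample(pooled, na, replace = TRUE),
                   sample(pooled, nb, replace = TRUE))
    }
  }, numeric(1)))
  p <- (1 + sum(Dstar >= D - 1e-12)) / (B + 1)
  structure(list(D = D, p = p, B = B, seed = seed, method = method,
                 n_a = na, n_b = nb),
            class = "ks_permutation")
}

#' @export
print.ks_permutation <- function(x, ...) {
  cat(sprintf("Two-sample K-S test (%s null, B = %d)\n", x$method, x$B))
  cat(sprintf("  n = %d vs %d;  D = %.4f;  p = %.4g\n",
              x$n_a, x$n_b, x$D, x$p))
  invisible(x)
}

#' Extract the beneficial tail of a DFE sample
#'
#' Selects beneficial mutations (default rule: `w > 1`, no significance
#' filter), converts to selection coefficients `s = w - 1`, and shifts the
#' threshold to the smallest observed beneficial `s`, returning exceedances
#' `x = s - min(s) >= 0` for extreme-value fitting. The minimal observation
#' sits exactly at the shifted threshold (`x = 0`) and carries no
#' information about the exceedance distribution, so it is dropped from the
#' likelihood by default; `drop_minimum = FALSE` keeps it.
#'
#' @param sample data.frame with a `w` column (e.g. one element of
#'   [build_dfe()], or a pooled sample), or a numeric vector of `w`.
#' @param rule function of `w` returning the beneficial indicator; default
#'   `w > 1`.
#' @param drop_minimum drop the observation at the shifted threshold.
#' @return list with `x` (exceedances), `threshold` (the minimal beneficial
#'   `s`), `n_beneficial`, `n_tail`, `dropped_minimum`.
#' @export
beneficial_tail <- function(sample, rule = function(w) w > 1,
                            drop_minimum = TRUE) {
  w <- if (is.data.frame(sample)) sample$w else as.numeric(sample)
  s <- w[rule(w)] - 1
  if (length(s) == 0) stop("no beneficial observations under the rule")
  if (length(s) < 3) stop("fewer than 3 beneficial observations: tail fit unsupported")
  thr <- min(s)
  x <- s - thr
  dropped <- FALSE
  if (drop_minimum) {
    x <- x[-which.min(x)]
    dropped <- TRUE
    message("threshold shifted to smallest beneficial s = ",
            format(thr), "; minimal observation dropped from likelihood")
  }
  list(x = x, threshold = thr, n_beneficial = length(s),
       n_tail = length(x), dropped_minimum = dropped)
}
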