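#' Linear model with permutation-of-residuals inference
#'
#' Ordinary least squares with per-term p-values from residual permutation.
#' For each tested term the default scheme is reduced-model (Freedman-Lane
#' style) permutation: the model *without* the term is fitted, its residuals
#' are permuted and added back to its fitted values, the full model is
#' refitted to each permuted response, and the term's partial F statistic is
#' compared with the observed one. P-values use the add-one convention
#' `(1 + #\{F* >= F\}) / (B + 1)` and therefore never reach 0. A raw
#' response-permutation scheme is available via `scheme = "raw"`.
#'
#' Partial F statistics are invariant to affine rescaling of the response
#' and predictors, so permutation p-values are too (at a fixed seed).
#'
#' @param formula model formula.
#' @param data data frame; rows with missing values in model variables are
#'   dropped listwise (count reported in the result).
#' @param B number of permutations.
#' @param seed RNG seed (NULL = current stream).
#' @param tested character vector of term labels to test (default: all
#'   non-intercept terms).
#' @param scheme `"reduced"` (permute reduced-model residuals) or `"raw"`
#'   (permute the response).
#' @return object of class `"permlm"`: `fit` (the `lm`), `coefficients`,
#'   `adj_r_squared`, `p_perm` (named per tested term), `f_obs`, `B`,
#'   `seed`, `n`, `n_dropped`, `scheme`.
#' @examples
#' d <- data.frame(x = 1:20, y = 1:20 + rnorm(20))
#' permlm(y ~ x, d, B = 199, seed = 1)
#' @export
permlm <- function(formula, data, B = 10000, seed = NULL, tested = NULL,
                   scheme = c("reduced", "raw")) {
  scheme <- match.arg(scheme)
  stopifnot(B >= 1)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0)
    stop("variables not in data: ", paste(missing_vars, collapse = ", "))
  cc <- complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]

  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2) stop("need at least p + 2 complete rows (have ", n, ")")
  if (qr(X)$rank < p)
    stop("rank-deficient design: collinear or duplicated predictors")

  fit <- lm(formula, data = data)
  asgn <- attr(X, "assign")
  labels <- attr(terms(mf), "term.labels")
  if (is.null(tested)) tested <- labels
  if (!all(tested %in% labels))
    stop("tested terms not in model: ",
         paste(setdiff(tested, labels), collapse = ", "))

  qr_f <- qr(X)
  Qf <- qr.Q(qr_f)
  rss_f_obs <- sum(lm.fit(X, y)$residuals^2)

  # partial F with explicit degenerate cases: a perfectly fitted response
  # gives F = Inf, a response the term cannot improve on at zero residual
  # variance gives F = 0
  fstat <- function(rss_r, rss_f, q, scale) {
    num <- (rss_r - rss_f) / q
    den <- rss_f / (n - p)
    eps <- 1e-12 * pmax(scale, 1)
    ifelse(den <= eps, ifelse(num <= eps, 0, Inf), num / den)
  }

  p_perm <- f_obs <- setNames(numeric(length(tested)), tested)
  perm_idx <- with_seed(seed, {
    matrix(replicate(B, sample.int(n)), nrow = n)
  })

  for (tm in tested) {
    j <- which(labels == tm)
    cols_drop <- which(asgn == j)
    q <- length(cols_drop)
    Xr <- X[, -cols_drop, drop = FALSE]
    fit_r <- lm.fit(Xr, y)
    rss_r_obs <- sum(fit_r$residuals^2)
    Fo <- fstat(rss_r_obs, rss_f_obs, q, sum(y^2))
    f_obs[tm] <- Fo

    if (scheme == "reduced") {
      base <- fit_r$fitted.values
      e <- fit_r$residuals
    } else {
      base <- rep(0, n)
      e <- y
    }
    Ystar <- base + matrix(e[perm_idx], nrow = n)
    # RSS under full and reduced models for all permuted responses at once
    Qr <- qr.Q(qr(Xr))
    tot <- colSums(Ystar^2)
    rss_f <- tot - colSums((crossprod(Qf, Ystar))^2)
    rss_r <- tot - colSums((crossprod(Qr, Ystar))^2)
    Fstar <- fstat(rss_r, rss_f, q, tot)
    p_perm[tm] <- (1 + sum(Fstar >= Fo)) / (B + 1)
  }

  out <- list(fit = fit,
              coefficients = coef(fit),
              adj_r_squared = suppressWarnings(summary(fit)$adj.r.squared),
              p_perm = p_perm, f_obs = f_obs,
              B = B, seed = seed, n = n, n_dropped = n_dropped,
              scheme = scheme, formula = formula)
  class(out) <- "permlm"
  out
}

#' @export
print.permlm <- function(x, ...) {
  cat("Permutation-of-residuals linear model:",
      deparse(x$formula), "\n")
  cat(sprintf("  n = %d (%d dropped), B = %d, scheme = %s\n",
              x$n, x$n_dropped, x$B, x$scheme))
  cat(sprintf("  adjusted R-squared = %.4f\n", x$adj_r_squared))
  for (tm in names(x$p_perm))
    cat(sprintf("  %s: F = %.4f, permutation p = %.4g\n",
                tm, x$f_obs[tm], x$p_perm[tm]))
  invisible(x)
}

#' @export
coef.permlm <- function(object, ...) object$coefficients

#' @export
summary.permlm <- function(object, ...) {
  s <- summary(object$fit)
  s$p_perm <- object$p_perm
  s
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed t-test assuming equal variances, as used for comparing
#' reporter-expression levels between mutant and wild-type constructs.
#' Degenerate inputs are handled explicitly: if the pooled variance is zero
#' and the group means are equal, `t = 0, p = 1`; if the pooled variance is
#' zero with unequal means the difference is infinitely many standard
#' errors, reported as `p = 0` (documented edge case).
#'
#' @param a,b numeric vectors, each of length `>= 2`.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
group_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (pooled <= .Machine$double.eps * max(abs(c(a, b)), 1)^2) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                p = if (eq) 1 else 0,
                df = length(a) + length(b) - 2,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}
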