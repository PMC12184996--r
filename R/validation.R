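#' Construct a per-mouse method profile
#'
#' One scalar stress value per mouse from one assessment method: the
#' automated score (0-10), the mean human-rater score (1-10), or fecal
#' corticosterone metabolites (ng per 50 mg feces).
#'
#' @param mouse_ids Unique identifiers, one per mouse.
#' @param values Finite numeric values, one per mouse.
#' @param method `"automated"`, `"raters"` or `"fcm"`.
#' @return Object of class `method_profile`.
#' @export
method_profile <- function(mouse_ids, values,
                           method = c("automated", "raters", "fcm")) {
  method <- match.arg(method)
  mouse_ids <- as.character(mouse_ids)
  if (anyDuplicated(mouse_ids)) stop("mouse_ids must be unique")
  if (length(mouse_ids) != length(values))
    stop("mouse_ids and values differ in length")
  if (!all(is.finite(values))) stop("values must be finite")
  structure(list(mouse_ids = mouse_ids, values = as.numeric(values),
                 method = method),
            class = "method_profile")
}

#' @export
print.method_profile <- function(x, ...) {
  cat(sprintf("<method_profile> %s, %d mice\n", x$method, length(x$values)))
  print(stats::setNames(round(x$values, 3), x$mouse_ids))
  invisible(x)
}

#' Min-max normalise a profile
#'
#' Rescales the profile values linearly onto `target_range` (default
#' \[0, 10\]), preserving order and all correlations (the map is affine).
#' Used to place methods with different natural units (e.g. hormone
#' concentrations) on the common stress scale.
#'
#' @param p A [method_profile()] with at least 2 distinct values.
#' @param target_range `c(lo, hi)`.
#' @return The rescaled profile.
#' @export
normalize_profile <- function(p, target_range = c(0, 10)) {
  stopifnot(inherits(p, "method_profile"))
  rng <- range(p$values)
  if (rng[1] == rng[2])
    stop("cannot normalise a constant profile (undefined rescale)")
  v <- (p$values - rng[1]) / (rng[2] - rng[1])
  p$values <- target_range[1] + v * (target_range[2] - target_range[1])
  p
}

align_profiles <- function(a, b) {
  stopifnot(inherits(a, "method_profile"), inherits(b, "method_profile"))
  if (length(a$values) != length(b$values) ||
      !setequal(a$mouse_ids, b$mouse_ids))
    stop("profiles cover different mice")
  b$values <- b$values[match(a$mouse_ids, b$mouse_ids)]
  b$mouse_ids <- a$mouse_ids
  list(a = a, b = b)
}

#' Pearson correlation between two method profiles
#'
#' Sample Pearson r between two per-mouse profiles, aligned by mouse id,
#' with the two-sided p-value from the t transform
#' `t = r * sqrt((n-2)/(1-r^2))`.
#'
#' @param a,b [method_profile()] objects covering the same mice (n >= 3).
#' @return List with `r`, `p`, and `n`.
#' @export
profile_pearson <- function(a, b) {
  al <- align_profiles(a, b)
  x <- al$a$values; y <- al$b$values
  n <- length(x)
  if (n < 3) stop("need at least 3 mice")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance profile: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Cohen's kappa for ordinal ratings
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` between two
#' raters, with unweighted, linear or quadratic agreement weights over the
#' ordinal category scale. With more than two raters the statistic is the
#' mean over all rater pairs (Cohen's kappa is strictly pairwise).
#'
#' @param ratings Raters x items matrix of ordinal ratings.
#' @param weighting `"linear"` (default, suits an ordinal 1-10 scale),
#'   `"unweighted"`, or `"quadratic"`.
#' @param levels The full ordinal category scale; defaults to the sorted
#'   unique ratings observed.
#' @return Mean pairwise kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(ratings,
                         weighting = c("linear", "unweighted", "quadratic"),
                         levels = NULL) {
  weighting <- match.arg(weighting)
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2) stop("need at least 2 raters (rows)")
  if (is.null(levels)) levels <- sort(unique(as.vector(ratings)))
  k <- length(levels)
  agree_w <- if (k == 1) {
    matrix(1, 1, 1)
  } else {
    d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
    switch(weighting,
           unweighted = (d == 0) * 1,
           linear = 1 - d,
           quadratic = 1 - d^2)
  }
  pair_kappa <- function(r1, r2) {
    i1 <- match(r1, levels); i2 <- match(r2, levels)
    if (anyNA(i1) || anyNA(i2)) stop("ratings outside the supplied levels")
    n <- length(i1)
    O <- matrix(0, k, k)
    for (j in seq_len(n)) O[i1[j], i2[j]] <- O[i1[j], i2[j]] + 1
    O <- O / n
    E <- rowSums(O) %o% colSums(O)
    po <- sum(agree_w * O)
    pe <- sum(agree_w * E)
    if (abs(1 - pe) < .Machine$double.eps^0.5) {
      if (abs(po - 1) < .Machine$double.eps^0.5) return(1)
      stop("expected agreement is 1 but observed agreement is not; ",
           "kappa undefined (single category used by all raters)")
    }
    (po - pe) / (1 - pe)
  }
  pairs <- utils::combn(nrow(ratings), 2)
  mean(apply(pairs, 2, function(pr)
    pair_kappa(ratings[pr[1], ], ratings[pr[2], ])))
}

#' Monte Carlo identity-shuffle test between two profiles
#'
#' Tests whether the agreement between two per-mouse stress profiles
#' exceeds what identity-blind chance produces: the mouse-id assignment of
#' the test profile is permuted uniformly at random `n_sim` times, the
#' similarity statistic (Pearson r by default) is recomputed under each
#' permutation, and the p-value is the add-one permutation estimator
#' `p = (1 + #\{null >= observed\}) / (n_sim + 1)` (never exactly zero).
#'
#' @param test,reference [method_profile()] objects over the same mice
#'   (n >= 3).
#' @param n_sim Number of random permutations (default 10000).
#' @param seed Optional RNG seed for reproducibility.
#' @param statistic `"pearson"` or `"neg_mean_abs_diff"` (negated mean
#'   absolute difference, for profiles already on a common scale).
#' @return List with `observed`, `p`, `n_sim`, and the vector of `null`
#'   statistics.
#' @export
monte_carlo_id_shuffle <- function(test, reference, n_sim = 10000,
                                   seed = NULL,
                                   statistic = c("pearson", "neg_mean_abs_diff")) {
  statistic <- match.arg(statistic)
  if (n_sim < 1) stop("n_sim must be >= 1")
  al <- align_profiles(reference, test)
  x <- al$a$values   # reference
  y <- al$b$values   # test, aligned
  n <- length(x)
  if (n < 3) stop("need at least 3 mice")
  stat <- switch(statistic,
                 pearson = function(yy) stats::cor(x, yy),
                 neg_mean_abs_diff = function(yy) -mean(abs(x - yy)))
  observed <- stat(y)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_sim), function(i) stat(y[sample.int(n)]), numeric(1))
  p <- (1 + sum(null >= observed)) / (n_sim + 1)
  list(observed = observed, p = p, n_sim = n_sim, null = null,
       statistic = statistic)
}
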