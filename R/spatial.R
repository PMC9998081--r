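# Resolve a feature argument to a numeric vector of length n: either a track
# name on the fold or a numeric/logical/integer vector.
resolve_track <- function(fold, x) {
  if (is.character(x) && length(x) == 1L) {
    if (is.null(fold$tracks[[x]])) {
      stop(sprintf("value error: no track named '%s'", x))
    }
    x <- fold$tracks[[x]]
  }
  as.numeric(x)
}

check_feature <- function(x, n) {
  if (length(x) != n) {
    stop(sprintf("value error: feature length %d does not match %d residues",
                 length(x), n))
  }
  if (stats::sd(x) == 0) {
    stop("degenerate-input error: feature has zero variance")
  }
  invisible(x)
}

# Internal pieces of the Getis-Ord statistic that do not change under
# conditional permutation: per-residue weighted-sum offsets and denominators.
# For the self-inclusive (G*) variant the global mean/sd of x are used; the
# plain G variant excludes residue i from its own sums and moments.
.getis_parts <- function(x, W) {
  w <- W$w
  n <- length(x)
  Swi <- rowSums(w)
  S1 <- rowSums(w^2)
  if (W$include_self) {
    xbar <- rep(mean(x), n)
    s <- rep(sqrt(mean(x^2) - mean(x)^2), n)
    m <- n
  } else {
    diag(w) <- 0
    Swi <- rowSums(w)
    S1 <- rowSums(w^2)
    xbar <- (sum(x) - x) / (n - 1)
    s <- sqrt(pmax((sum(x^2) - x^2) / (n - 1) - xbar^2, 0))
    m <- n - 1
  }
  den <- s * sqrt(pmax((m * S1 - Swi^2) / (m - 1), 0))
  list(w = w, Swi = Swi, den = den, xbar = xbar)
}

# 0/0 from degenerate weight rows (e.g. the complete self-inclusive graph,
# where the variance term vanishes together with the numerator) is defined
# as 0; a genuinely nonzero numerator over a zero denominator is +-Inf.
.safe_ratio <- function(num, den) {
  ifelse(den > 0, num / den,
         ifelse(abs(num) <= 1e-12, 0, sign(num) * Inf))
}

#' Getis-Ord local clustering statistic
#'
#' Per-residue z-valued statistic measuring whether a residue and its spatial
#' neighbours carry jointly high (positive z) or low (negative z) feature
#' values. With self-inclusive weights (`include_self = TRUE` at weight
#' construction) this is the G* variant; otherwise the plain G variant, which
#' excludes residue i from its own sums and from the mean and standard
#' deviation used for residue i.
#'
#' @param x Per-residue numeric feature (nonconstant), or a track name when a
#'   fold is attached to the weights by the caller.
#' @param W A [build_weights()] object.
#' @return Numeric z vector of length n.
#' @export
getis_ord <- function(x, W) {
  stopifnot(inherits(W, "spatial_weights"))
  x <- as.numeric(x)
  check_feature(x, nrow(W$w))
  pp <- .getis_parts(x, W)
  num <- as.numeric(pp$w %*% x) - pp$xbar * pp$Swi
  .safe_ratio(num, pp$den)
}

#' Local Moran's I
#'
#' Anselin-style local decomposition of Moran's I:
#' `I_i = (x_i - xbar) / m2 * sum_j w_ij (x_j - xbar)` with
#' `m2 = sum_k (x_k - xbar)^2 / n`. The self-weight is forced to zero.
#' Positive values mark residues similar to their neighbours (both high or
#' both low), negative values mark local dissimilarity.
#'
#' @inheritParams getis_ord
#' @return Numeric I vector of length n.
#' @export
local_moran <- function(x, W) {
  stopifnot(inherits(W, "spatial_weights"))
  x <- as.numeric(x)
  n <- nrow(W$w)
  check_feature(x, n)
  w <- W$w
  diag(w) <- 0
  xc <- x - mean(x)
  m2 <- sum(xc^2) / n
  (xc / m2) * as.numeric(w %*% xc)
}

#' Conditional permutation p-values for a local statistic
#'
#' For each residue i the feature value x_i is held fixed while the remaining
#' values are randomly permuted over the remaining positions; the observed
#' local statistic is compared against `n_perm` such draws. The p-value uses
#' the +1/+1 correction, `p_i = (1 + #[stat_perm >= stat_obs]) / (1 + n_perm)`
#' for `alternative = "greater"` (`|.|` on both sides for `"two_sided"`), so
#' p is never 0 and never below `1/(n_perm + 1)`. Deterministic under `seed`;
#' the caller's RNG state is left untouched.
#'
#' @inheritParams getis_ord
#' @param method `"getis_ord"` or `"moran"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer RNG seed.
#' @param alternative `"greater"` (high-value clustering) or `"two_sided"`.
#' @return Numeric p vector in `(0, 1]`.
#' @export
permutation_pvalues <- function(x, W, method = c("getis_ord", "moran"),
                                n_perm = 999, seed = 42,
                                alternative = c("greater", "two_sided")) {
  stopifnot(inherits(W, "spatial_weights"))
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!is.numeric(n_perm) || n_perm < 1) stop("value error: n_perm must be >= 1")
  x <- as.numeric(x)
  n <- nrow(W$w)
  check_feature(x, n)

  if (method == "getis_ord") {
    pp <- .getis_parts(x, W)
    obs <- .safe_ratio(as.numeric(pp$w %*% x) - pp$xbar * pp$Swi, pp$den)
    w <- pp$w
  } else {
    obs <- local_moran(x, W)
    w <- W$w
    diag(w) <- 0
    xbar <- mean(x)
    m2 <- sum((x - xbar)^2) / n
  }

  p <- numeric(n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      xm <- x[-i]
      P <- vapply(seq_len(n_perm), function(k) sample(xm), numeric(n - 1L))
      wi <- w[i, -i]
      if (method == "getis_ord") {
        ws <- as.numeric(wi %*% P) + w[i, i] * x[i]
        stat <- .safe_ratio(ws - pp$xbar[i] * pp$Swi[i], rep(pp$den[i], n_perm))
      } else {
        stat <- ((x[i] - xbar) / m2) * as.numeric(wi %*% (P - xbar))
      }
      hits <- if (alternative == "greater") {
        sum(stat >= obs[i])
      } else {
        sum(abs(stat) >= abs(obs[i]))
      }
      p[i] <- (1 + hits) / (1 + n_perm)
    }
  })
  p
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjustment of permutation p-values; residues with adjusted value
#' q <= `rate` are flagged.
#'
#' @param p Numeric p-values in `(0, 1]`.
#' @param rate Target false discovery rate in `(0, 1)`.
#' @return List with `q` (adjusted values) and `reject` (logical flags).
#' @export
bh_fdr <- function(p, rate = 0.05) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("value error: p-values must lie in (0, 1]")
  }
  if (!is.numeric(rate) || rate <= 0 || rate >= 1) {
    stop("value error: rate must lie in (0, 1)")
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q <= rate)
}

#' Detect feature hotspots on a protein structure
#'
#' The full hotspot pipeline: CA coordinates -> neighbour weights -> local
#' autocorrelation statistic -> conditional permutation p-values ->
#' Benjamini-Hochberg FDR. A residue is flagged hot when its q-value is at
#' most `false_discovery_rate` *and* its local statistic is positive, i.e.
#' high-value clustering; significant cold-spots are reported in the
#' statistic but not flagged.
#'
#' Defaults follow field convention: self-inclusive binary weights within an
#' 8 A CA radius (the G* variant) for `method = "getis_ord"`, and
#' row-standardized radius weights without self for `method = "moran"`;
#' 999 permutations, one-sided.
#'
#' @param fold A `fold` object.
#' @param x Per-residue feature: numeric/0-1 vector of length `length(fold)`,
#'   or the name of an attached track.
#' @param false_discovery_rate Target FDR, default 0.05.
#' @param method `"getis_ord"` (default) or `"moran"`.
#' @param weights_method,radius,k,lambda Passed to [build_weights()].
#' @param include_self,row_standardize Override the per-method weight
#'   defaults described above (`NULL` = use them).
#' @param n_perm,seed,alternative Passed to [permutation_pvalues()].
#' @return A `hotspot_result`: list with `statistic`, `p`, `q`, `hot`,
#'   `method`, `n_perm`, `seed`, `fdr`.
#' @export
find_hotspots <- function(fold, x, false_discovery_rate = 0.05,
                          method = c("getis_ord", "moran"),
                          weights_method = "binary_radius",
                          radius = 8, k = 6, lambda = 5,
                          include_self = NULL, row_standardize = NULL,
                          n_perm = 999, seed = 42,
                          alternative = c("greater", "two_sided")) {
  stopifnot(inherits(fold, "fold"))
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  x <- resolve_track(fold, x)
  if (is.null(include_self)) include_self <- method == "getis_ord"
  if (is.null(row_standardize)) row_standardize <- method == "moran"

  W <- build_weights(ca_coords(fold), method = weights_method,
                     radius = radius, k = k, lambda = lambda,
                     include_self = include_self,
                     row_standardize = row_standardize)
  stat <- if (method == "getis_ord") getis_ord(x, W) else local_moran(x, W)
  p <- permutation_pvalues(x, W, method = method, n_perm = n_perm,
                           seed = seed, alternative = alternative)
  fr <- bh_fdr(p, false_discovery_rate)
  structure(
    list(statistic = stat, p = p, q = fr$q,
         hot = fr$reject & stat > 0,
         method = method, n_perm = as.integer(n_perm), seed = seed,
         fdr = false_discovery_rate, weights = W),
    class = "hotspot_result")
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat(sprintf("<hotspot_result> %s, %d residues, %d hot (fdr = %g, n_perm = %d)\n",
              x$method, length(x$statistic), sum(x$hot), x$fdr, x$n_perm))
  invisible(x)
}

#' Spherical sliding-window aggregation
#'
#' Aggregates a per-residue feature within a sphere slid along the folded
#' chain: `out[i]` is the `agg` of `x` over all residues whose CA lies within
#' `radius` of residue i's CA (always including residue i itself).
#'
#' @param fold A `fold` object.
#' @param x Feature vector or track name.
#' @param radius Window radius in A (>= 0; 0 returns `x` unchanged).
#' @param agg `"mean"`, `"sum"` or `"max"`.
#' @return Numeric vector of length n.
#' @export
sliding_window <- function(fold, x, radius, agg = c("mean", "sum", "max")) {
  stopifnot(inherits(fold, "fold"))
  if (!is.character(agg) || !all(agg %in% c("mean", "sum", "max"))) {
    stop("value error: agg must be one of 'mean', 'sum', 'max'")
  }
  agg <- match.arg(agg)
  if (!is.numeric(radius) || radius < 0) stop("value error: radius must be >= 0")
  x <- resolve_track(fold, x)
  n <- length(fold)
  if (length(x) != n) {
    stop(sprintf("value error: feature length %d does not match %d residues",
                 length(x), n))
  }
  D <- as.matrix(stats::dist(ca_coords(fold)))
  f <- switch(agg, mean = mean, sum = sum, max = max)
  vapply(seq_len(n), function(i) f(x[D[i, ] <= radius]), numeric(1))
}
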