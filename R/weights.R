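#' Build residue neighbour weights
#'
#' Constructs the n x n spatial weight matrix over residues that defines each
#' residue's neighbourhood for the local autocorrelation statistics. Three
#' constructions are offered:
#'
#' * `"binary_radius"` — w_ij = 1 iff 0 < d(i,j) <= `radius` (distance band,
#'   the fixed-radius neighbourhood conventionally used on proteins);
#' * `"knn"` — w_ij = 1 iff j is among i's `k` nearest residues (ties broken
#'   by lower residue index; may be asymmetric);
#' * `"decay"` — w_ij = exp(-d(i,j) / `lambda`), a continuous neighbourhood
#'   that decays with distance.
#'
#' @param coords n x 3 coordinate matrix (A), typically [ca_coords()].
#' @param method Weight construction, see above.
#' @param radius Distance band in A (`binary_radius`); default 8, a standard
#'   CA-CA residue-contact radius.
#' @param k Number of neighbours (`knn`), in `[1, n-1]`.
#' @param lambda Decay scale in A (`decay`).
#' @param include_self Include the focal residue itself (diagonal weight 1)?
#'   Self-inclusive weights give the G* variant of the Getis-Ord statistic.
#' @param row_standardize Divide each nonzero row by its sum?
#' @return A `spatial_weights` object: list with the matrix `w`, `method`,
#'   `params`, `include_self`, `row_standardized`.
#' @export
build_weights <- function(coords,
                          method = c("binary_radius", "knn", "decay"),
                          radius = 8, k = 6, lambda = 5,
                          include_self = FALSE, row_standardize = FALSE) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("value error: need at least 2 residues")
  d <- unname(as.matrix(stats::dist(coords)))

  if (method == "binary_radius") {
    if (!is.numeric(radius) || radius <= 0) stop("value error: radius must be > 0")
    w <- (d > 0 & d <= radius) * 1
    if (any(rowSums(w) == 0)) {
      warning(sprintf("%d isolated residue(s) with no neighbour within %g A (zero weight row)",
                      sum(rowSums(w) == 0), radius))
    }
    params <- list(radius = radius)
  } else if (method == "knn") {
    if (!is.numeric(k) || k < 1 || k > n - 1) {
      stop("value error: k must lie in [1, n-1]")
    }
    k <- as.integer(k)
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      ord <- order(d[i, ], seq_len(n))  # distance, then lower index
      nb <- setdiff(ord, i)[seq_len(k)]
      w[i, nb] <- 1
    }
    params <- list(k = k)
  } else {
    if (!is.numeric(lambda) || lambda <= 0) stop("value error: lambda must be > 0")
    w <- exp(-d / lambda)
    diag(w) <- 0
    params <- list(lambda = lambda)
  }

  if (include_self) diag(w) <- 1
  if (row_standardize) {
    rs <- rowSums(w)
    nz <- rs > 0
    w[nz, ] <- w[nz, , drop = FALSE] / rs[nz]
  }

  structure(
    list(w = w, method = method, params = params,
         include_self = include_self, row_standardized = row_standardize),
    class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %s, n = %d, include_self = %s, row_standardized = %s\n",
              x$method, nrow(x$w), x$include_self, x$row_standardized))
  invisible(x)
}
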