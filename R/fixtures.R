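# Deterministic synthetic structures. These are first-class generators used
# both in examples and throughout the test suite: CA-only geometry is enough
# substrate for every spatial operation, and nothing here needs a download.

# assemble a CA-only single-atom-per-residue fold from a coordinate matrix
.ca_fold <- function(coords, chain = "A", res_name = "GLY",
                     b_factor = 0, source = "synthetic") {
  n <- nrow(coords)
  atoms <- data.frame(
    serial = seq_len(n),
    name = "CA",
    element = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1,
    b_factor = rep_len(b_factor, n),
    chain = rep_len(chain, n),
    author_number = seq_len(n),
    insertion_code = "",
    res_name = rep_len(res_name, n),
    is_hetero = FALSE,
    res_index = seq_len(n) - 1L,
    stringsAsFactors = FALSE
  )
  new_fold(atoms, source = source)
}

#' Ideal helix fixture
#'
#' CA-only helix: residue i (0-based) sits at
#' `(radius cos(i twist), radius sin(i twist), i rise)`. Defaults mimic an
#' alpha-helix (rise 1.5 A/residue, twist 100 deg, radius 2.3 A).
#'
#' @param n Number of residues (>= 1).
#' @param rise Axial rise per residue (A).
#' @param twist Turn per residue (degrees).
#' @param radius Helix radius (A).
#' @return A single-chain GLY `fold`.
#' @export
make_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  if (!is.numeric(n) || n < 1) stop("value error: n must be >= 1")
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  ang <- i * twist * pi / 180
  .ca_fold(cbind(radius * cos(ang), radius * sin(ang), i * rise),
           source = sprintf("synthetic helix n=%d", n))
}

#' Two Gaussian blobs fixture
#'
#' Two isotropic Gaussian point clouds (sd 2 A) centred at the origin and at
#' `(separation, 0, 0)`; deterministic under `seed` without disturbing the
#' caller's RNG state.
#'
#' @param n1,n2 Residues per blob.
#' @param separation Centre-to-centre distance (A), > 0 required by the
#'   canonical two-cluster use; 0 yields one merged cloud and is allowed.
#' @param sd Spread of each blob (A).
#' @param seed Integer seed.
#' @return A single-chain GLY `fold` of `n1 + n2` residues (blob 1 first).
#' @export
make_two_blob <- function(n1 = 20, n2 = 20, separation = 50, sd = 2,
                          seed = 1) {
  if (!is.numeric(separation) || separation < 0) {
    stop("value error: separation must be >= 0")
  }
  coords <- withr::with_seed(seed, {
    rbind(
      matrix(stats::rnorm(3 * n1, 0, sd), ncol = 3),
      cbind(stats::rnorm(n2, separation, sd),
            stats::rnorm(n2, 0, sd), stats::rnorm(n2, 0, sd))
    )
  })
  .ca_fold(coords,
           source = sprintf("synthetic two_blob sep=%g seed=%d",
                            separation, seed))
}

#' Two parallel chains fixture
#'
#' Two straight parallel strands (chains A and B) `separation` A apart along
#' y, each residue carrying a CA and a CB atom (the CB offset along z makes
#' `min_heavy` distances differ from CA-CA ones). Substrate for complex
#' geometry and interface tests.
#'
#' @param n_per_chain Residues per chain.
#' @param separation Inter-chain distance (A).
#' @param spacing Residue spacing along x (A).
#' @return A two-chain ALA `fold`.
#' @export
make_two_chain <- function(n_per_chain = 10, separation = 4, spacing = 3.8) {
  n <- as.integer(n_per_chain)
  one_chain <- function(ch, y0, serial0, res0) {
    i <- seq_len(n) - 1L
    data.frame(
      serial = serial0 + seq_len(2L * n) - 1L,
      name = rep(c("CA", "CB"), n),
      element = "C",
      x = rep(i * spacing, each = 2),
      y = y0,
      z = rep(c(0, 1.5), n),
      occupancy = 1,
      b_factor = 0,
      chain = ch,
      author_number = rep(i + 1L, each = 2),
      insertion_code = "",
      res_name = "ALA",
      is_hetero = FALSE,
      res_index = rep(res0 + i, each = 2),
      stringsAsFactors = FALSE
    )
  }
  atoms <- rbind(one_chain("A", 0, 1L, 0L),
                 one_chain("B", separation, 2L * n + 1L, n))
  new_fold(atoms, source = "synthetic two_chain")
}

#' Plant a spatially contiguous binary feature
#'
#' Binary track with 1 on every residue whose CA lies within `radius` of the
#' CA of `center_index` — a synthetic stand-in for a spatially clustered
#' signal such as sites under positive selection.
#'
#' @param fold A `fold` object.
#' @param center_index 0-based residue index of the blob centre.
#' @param radius Blob radius (A); 0 marks only the centre.
#' @return Integer 0/1 vector of length `length(fold)`.
#' @export
plant_feature <- function(fold, center_index, radius) {
  stopifnot(inherits(fold, "fold"))
  n <- length(fold)
  if (!is.numeric(center_index) || center_index < 0 || center_index > n - 1) {
    stop(sprintf("value error: center_index %s out of range [0, %d]",
                 as.character(center_index), n - 1))
  }
  cc <- ca_coords(fold)
  d <- sqrt(colSums((t(cc) - cc[center_index + 1L, ])^2))
  as.integer(d <= radius)
}
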