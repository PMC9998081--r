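`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles and hand-built PDB text fixtures. Everything here is
# deliberately written as plain loops over the defining formulas, sharing no
# code with the package internals it checks.

## ---- PDB text -------------------------------------------------------------

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     b = 0, occ = 1, icode = " ", altloc = " ",
                     element = "C", record = "ATOM") {
  nm <- if (nchar(name) >= 4) name else paste0(" ", formatC(name, width = -3))
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, icode,
          x, y, z, occ, b, element)
}

# two residues: GLY at the origin, ALA at (3.8, 0, 0)
fixture_two_res <- function() {
  paste(c(
    pdb_line(1, "N", "GLY", "A", 1, -1.2, 0.5, 0, element = "N"),
    pdb_line(2, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(3, "CA", "ALA", "A", 2, 3.8, 0, 0),
    pdb_line(4, "CB", "ALA", "A", 2, 4.3, 1.4, 0),
    "TER", "END"), collapse = "\n")
}

fixture_two_models <- function() {
  paste(c(
    "MODEL     1",
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL     2",
    pdb_line(3, "CA", "GLY", "A", 1, 0, 0, 1),
    pdb_line(4, "CA", "GLY", "A", 2, 3.8, 0, 1),
    pdb_line(5, "CA", "GLY", "A", 3, 7.6, 0, 1),
    "ENDMDL", "END"), collapse = "\n")
}

fixture_altloc <- function() {
  paste(c(
    pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, altloc = "A", occ = 0.6),
    pdb_line(2, "CA", "SER", "A", 1, 9, 9, 9, altloc = "B", occ = 0.4),
    pdb_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    "END"), collapse = "\n")
}

fixture_three_chains <- function() {
  lines <- character(0)
  s <- 0
  for (ch in c("A", "B", "C")) {
    off <- match(ch, c("A", "B", "C")) * 20
    for (i in 1:2) {
      s <- s + 1
      lines <- c(lines, pdb_line(s, "CA", "GLY", ch, i, off + i * 3.8, 0, 0))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

## ---- spatial statistics ----------------------------------------------------

brute_getis <- function(x, W) {
  w <- W$w
  n <- length(x)
  z <- numeric(n)
  for (i in seq_len(n)) {
    if (W$include_self) {
      wi <- w[i, ]
      xbar <- mean(x)
      s <- sqrt(sum((x - xbar)^2) / n)
      m <- n
      xs <- x
    } else {
      wi <- w[i, ]
      wi[i] <- 0
      xbar <- mean(x[-i])
      s <- sqrt(sum((x[-i] - xbar)^2) / (n - 1))
      m <- n - 1
      xs <- x
    }
    S <- sum(wi)
    S1 <- sum(wi^2)
    num <- sum(wi * xs) - xbar * S
    den <- s * sqrt((m * S1 - S^2) / (m - 1))
    z[i] <- if (den > 0) num / den else if (abs(num) < 1e-12) 0 else sign(num) * Inf
  }
  z
}

brute_moran <- function(x, W) {
  w <- W$w
  n <- length(x)
  xbar <- mean(x)
  m2 <- sum((x - xbar)^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i) acc <- acc + w[i, j] * (x[j] - xbar)
    }
    out[i] <- (x[i] - xbar) / m2 * acc
  }
  out
}

# global Moran's I for the additivity identity sum_i I_i = S0 * I_global
global_moran <- function(x, W) {
  w <- W$w
  diag(w) <- 0
  n <- length(x)
  xbar <- mean(x)
  S0 <- sum(w)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + w[i, j] * (x[i] - xbar) * (x[j] - xbar)
  }
  (n / S0) * num / sum((x - xbar)^2)
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# exhaustive conditional-permutation p-values on tiny fixtures
exact_perm_p <- function(x, W, method = "getis_ord") {
  stat_fn <- if (method == "getis_ord") brute_getis else brute_moran
  obs <- stat_fn(x, W)
  n <- length(x)
  p <- numeric(n)
  for (i in seq_len(n)) {
    perms <- all_perms(x[-i])
    hits <- 0
    for (pp in perms) {
      xp <- x
      xp[-i] <- pp
      if (stat_fn(xp, W)[i] >= obs[i]) hits <- hits + 1
    }
    p[i] <- hits / length(perms)
  }
  p
}

# independent Benjamini-Hochberg step-up
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    prev <- min(prev, m * p[o[r]] / r)
    q[o[r]] <- prev
  }
  pmin(q, 1)
}

## ---- geometry / clustering -------------------------------------------------

brute_sliding <- function(coords, x, radius, f) {
  n <- nrow(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (j in seq_len(n)) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= radius) {
        vals <- c(vals, x[j])
      }
    }
    out[i] <- f(vals)
  }
  out
}

# brute-force interface scan over all heavy atom pairs
brute_interface <- function(fold, chain_a, chain_b, cutoff) {
  a <- fold$atoms[!(fold$atoms$element %in% c("H", "D")), ]
  aa <- a[a$chain == chain_a, ]
  ab <- a[a$chain == chain_b, ]
  hits <- integer(0)
  for (ri in unique(aa$res_index)) {
    ra <- aa[aa$res_index == ri, ]
    found <- FALSE
    for (p in seq_len(nrow(ra))) {
      for (q in seq_len(nrow(ab))) {
        d <- sqrt((ra$x[p] - ab$x[q])^2 + (ra$y[p] - ab$y[q])^2 +
                    (ra$z[p] - ab$z[q])^2)
        if (d <= cutoff) found <- TRUE
      }
    }
    if (found) hits <- c(hits, as.integer(ri))
  }
  sort(hits)
}

# second implementation of the MCL update rule (plain loops)
ref_mcl_partition <- function(adj, inflation = 2, expansion = 2,
                              max_iter = 100, tol = 1e-6) {
  n <- nrow(adj)
  M <- adj
  for (i in seq_len(n)) M[i, i] <- 1
  colnorm <- function(M) {
    for (j in seq_len(ncol(M))) M[, j] <- M[, j] / sum(M[, j])
    M
  }
  M <- colnorm(M)
  for (it in seq_len(max_iter)) {
    Mp <- M
    for (e in seq_len(expansion - 1)) Mp <- Mp %*% M
    Mp <- colnorm(Mp^inflation)
    Mp[Mp < 1e-6] <- 0
    done <- max(abs(Mp - M)) < tol
    M <- Mp
    if (done) break
  }
  # partition: label propagation over the support graph of attractor rows
  att <- which(rowSums(M) > 0)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (j in seq_len(n)) {
      supp <- att[M[att, j] > 0]
      grp <- min(lab[c(j, supp)])
      for (k in c(j, supp)) {
        if (lab[k] != grp) {
          lab[k] <- grp
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# two label vectors describe the same partition (noise -1 respected)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == -1) == (b == -1))) return(FALSE)
  for (i in seq_along(a)) {
    for (j in seq_along(a)) {
      if (a[i] != -1 && a[j] != -1 &&
          ((a[i] == a[j]) != (b[i] == b[j]))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# random spatial weights over random coordinates, for property sweeps
random_fixture <- function(n, seed) {
  withr::with_seed(seed, {
    coords <- matrix(stats::rnorm(3 * n, sd = 6), ncol = 3)
    x <- stats::rnorm(n)
    method <- sample(c("binary_radius", "knn", "decay"), 1)
    W <- build_weights(coords, method = method,
                       radius = stats::runif(1, 6, 15),
                       k = sample(1:(n - 1), 1),
                       lambda = stats::runif(1, 2, 8),
                       include_self = sample(c(TRUE, FALSE), 1),
                       row_standardize = sample(c(TRUE, FALSE), 1))
    list(coords = coords, x = x, W = W)
  })
}
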