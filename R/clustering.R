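# ---- HDBSCAN-style density clustering -------------------------------------
#
# Single-linkage hierarchy on mutual-reachability distances, condensed by
# minimum cluster size, clusters extracted by excess-of-mass stability.
# Noise is labelled -1. The root cluster is never selected unless
# `allow_single_cluster`, matching the convention of density-clustering
# libraries (otherwise the root, which always contains everything, would
# swallow all structure).

# leaves (1-based point indices) under a node of an hclust merge tree;
# node > 0 refers to merge row, node < 0 to leaf -node.
.hc_leaves <- function(merge, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd < 0) out <- c(out, -nd) else stack <- c(stack, merge[nd, ])
  }
  out
}

hdbscan_points <- function(coords, min_cluster_size = 5,
                           min_samples = min_cluster_size,
                           allow_single_cluster = FALSE) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (min_cluster_size < 2) stop("value error: min_cluster_size must be >= 2")
  if (m < min_cluster_size) return(rep(-1L, m))

  D <- as.matrix(stats::dist(coords))
  core <- apply(D, 1, function(r) sort(r)[min_samples])  # self counts
  cc <- pmax(matrix(core, m, m), matrix(core, m, m, byrow = TRUE))
  M <- pmax(D, cc)
  diag(M) <- 0
  hc <- stats::hclust(stats::as.dist(M), method = "single")
  merge <- hc$merge
  height <- hc$height
  nsize <- integer(m - 1)   # merge rows only reference earlier rows
  for (t in seq_len(m - 1)) {
    a <- merge[t, 1]; b <- merge[t, 2]
    nsize[t] <- (if (a < 0) 1L else nsize[a]) + (if (b < 0) 1L else nsize[b])
  }

  # condensed tree: cluster 1 = root
  birth <- 0
  parent <- integer(0)        # parent cluster of cluster id
  cl_birth <- c(0)            # lambda at cluster birth
  children <- list(integer(0))
  pe_cluster <- integer(0); pe_point <- integer(0); pe_lambda <- numeric(0)
  ce_parent <- integer(0); ce_child <- integer(0)
  ce_lambda <- numeric(0); ce_size <- integer(0)

  node_size <- function(nd) if (nd < 0) 1L else nsize[nd]
  lam_of <- function(t) 1 / max(height[t], .Machine$double.eps)

  queue <- list(list(node = m - 1L, cluster = 1L))
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    nd <- item$node; cl <- item$cluster
    a <- merge[nd, 1]; b <- merge[nd, 2]
    lam <- lam_of(nd)
    sa <- node_size(a); sb <- node_size(b)
    big_a <- sa >= min_cluster_size
    big_b <- sb >= min_cluster_size
    if (big_a && big_b) {
      for (ch in list(a, b)) {
        new_id <- length(cl_birth) + 1L
        cl_birth <- c(cl_birth, lam)
        parent[new_id] <- cl
        children[[cl]] <- c(children[[cl]], new_id)
        children[[new_id]] <- integer(0)
        ce_parent <- c(ce_parent, cl); ce_child <- c(ce_child, new_id)
        ce_lambda <- c(ce_lambda, lam); ce_size <- c(ce_size, node_size(ch))
        if (ch > 0) {
          queue[[length(queue) + 1L]] <- list(node = ch, cluster = new_id)
        } else {
          # a bare leaf cannot reach min_cluster_size >= 2; unreachable
          pe_cluster <- c(pe_cluster, new_id)
          pe_point <- c(pe_point, -ch); pe_lambda <- c(pe_lambda, lam)
        }
      }
    } else if (big_a || big_b) {
      small <- if (big_a) b else a
      big <- if (big_a) a else b
      pts <- .hc_leaves(merge, small)
      pe_cluster <- c(pe_cluster, rep(cl, length(pts)))
      pe_point <- c(pe_point, pts)
      pe_lambda <- c(pe_lambda, rep(lam, length(pts)))
      if (big > 0) {
        queue[[length(queue) + 1L]] <- list(node = big, cluster = cl)
      } else {
        pe_cluster <- c(pe_cluster, cl)
        pe_point <- c(pe_point, -big); pe_lambda <- c(pe_lambda, lam)
      }
    } else {
      pts <- c(.hc_leaves(merge, a), .hc_leaves(merge, b))
      pe_cluster <- c(pe_cluster, rep(cl, length(pts)))
      pe_point <- c(pe_point, pts)
      pe_lambda <- c(pe_lambda, rep(lam, length(pts)))
    }
  }

  K <- length(cl_birth)
  lam_cap <- 1e12
  stab <- numeric(K)
  for (e in seq_along(pe_cluster)) {
    c0 <- pe_cluster[e]
    stab[c0] <- stab[c0] + min(pe_lambda[e], lam_cap) - cl_birth[c0]
  }
  for (e in seq_along(ce_parent)) {
    c0 <- ce_parent[e]
    stab[c0] <- stab[c0] +
      (min(ce_lambda[e], lam_cap) - cl_birth[c0]) * ce_size[e]
  }

  # excess-of-mass selection, children before parents
  sel <- rep(FALSE, K)
  score <- numeric(K)
  deselect_subtree <- function(cl) {
    for (ch in children[[cl]]) {
      sel[ch] <<- FALSE
      deselect_subtree(ch)
    }
  }
  for (cl in rev(seq_len(K))) {
    kids <- children[[cl]]
    if (length(kids) == 0L) {
      sel[cl] <- cl != 1L || allow_single_cluster
      score[cl] <- stab[cl]
    } else {
      sc <- sum(score[kids])
      if (stab[cl] >= sc && (cl != 1L || allow_single_cluster)) {
        sel[cl] <- TRUE
        deselect_subtree(cl)
        score[cl] <- stab[cl]
      } else {
        score[cl] <- sc
      }
    }
  }

  # map every condensed cluster to its nearest selected ancestor-or-self
  mapped <- rep(NA_integer_, K)
  for (cl in seq_len(K)) {
    mapped[cl] <- if (sel[cl]) {
      cl
    } else if (cl == 1L) {
      NA_integer_
    } else {
      mapped[parent[cl]]
    }
  }

  labels <- rep(-1L, m)
  for (e in seq_along(pe_cluster)) {
    tgt <- mapped[pe_cluster[e]]
    if (!is.na(tgt)) labels[pe_point[e]] <- tgt
  }
  labels
}

# ---- Markov clustering -----------------------------------------------------

#' Markov clustering (MCL) on an adjacency matrix
#'
#' From-scratch MCL: self-loops of weight 1 are added, columns normalized to
#' stochastic form, then the update {matrix power `expansion`, elementwise
#' power `inflation`, column renormalization, pruning of entries below 1e-6}
#' is iterated until the largest column change falls below `tol` or
#' `max_iter` is reached. Clusters are read off as connected attractor sets:
#' attractor rows retain mass, each node joins the cluster of the first (by
#' index) attractor that claims it, and attractors sharing any node are
#' merged.
#'
#' @param adjacency Symmetric nonnegative n x n matrix.
#' @param inflation Inflation exponent (> 1), controls granularity.
#' @param expansion Integer matrix-power (>= 2).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max absolute entry change.
#' @return A `cluster_labels` object; `params$converged` records whether the
#'   iteration converged within `max_iter`.
#' @export
mcl <- function(adjacency, inflation = 2, expansion = 2,
                max_iter = 100, tol = 1e-6) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stop("value error: adjacency must be square")
  if (any(adjacency < 0)) stop("value error: adjacency must be nonnegative")
  if (!isSymmetric(unname(adjacency), tol = 1e-8)) {
    stop("value error: adjacency must be symmetric")
  }
  if (!is.numeric(inflation) || inflation <= 1) {
    stop("value error: inflation must be > 1")
  }
  expansion <- as.integer(expansion)
  if (expansion < 2) stop("value error: expansion must be >= 2")
  prune <- 1e-6

  M <- adjacency
  diag(M) <- 1
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mp <- M
    for (e in seq_len(expansion - 1L)) Mp <- Mp %*% M   # power `expansion`
    Mp <- Mp^inflation
    Mp <- sweep(Mp, 2, colSums(Mp), "/")
    Mp[Mp < prune] <- 0
    delta <- max(abs(Mp - M))
    M <- Mp
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  attractors <- which(rowSums(M) > 0)
  # union-find over attractors: attractors sharing a column's support merge
  uf <- seq_len(n)
  find <- function(i) {
    while (uf[i] != i) i <- uf[i]
    i
  }
  for (j in seq_len(n)) {
    supp <- attractors[M[attractors, j] > 0]
    if (length(supp) > 1) {
      r <- find(supp[1])
      for (s in supp[-1]) uf[find(s)] <- r
    }
  }
  labels <- rep(-1L, n)
  for (j in seq_len(n)) {
    supp <- attractors[M[attractors, j] > 0]
    if (length(supp)) {
      labels[j] <- find(supp[1])          # first attractor by index
    }
  }
  labels <- renumber_labels(labels)
  new_cluster_labels(labels$labels, method = "mcl",
                     params = list(inflation = inflation,
                                   expansion = expansion,
                                   max_iter = max_iter, tol = tol,
                                   converged = converged))
}

# ---- common label plumbing -------------------------------------------------

# renumber arbitrary integer labels (noise = -1) to 0..K-1 by decreasing
# cluster size, ties by lowest member index
renumber_labels <- function(labels, order_index = seq_along(labels)) {
  ids <- sort(unique(labels[labels != -1L]))
  if (length(ids) == 0L) {
    return(list(labels = labels, k = 0L))
  }
  size <- vapply(ids, function(g) sum(labels == g), integer(1))
  minidx <- vapply(ids, function(g) min(order_index[labels == g]), numeric(1))
  ord <- ids[order(-size, minidx)]
  out <- labels
  for (r in seq_along(ord)) out[labels == ord[r]] <- r - 1L
  list(labels = out, k = length(ord))
}

new_cluster_labels <- function(labels, method, params) {
  structure(
    list(labels = as.integer(labels), method = method, params = params,
         n_clusters = length(unique(labels[labels != -1L]))),
    class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("<cluster_labels> %s: %d clusters over %d residues (%d noise)\n",
              x$method, x$n_clusters, length(x$labels),
              sum(x$labels == -1L)))
  invisible(x)
}

#' Point-density clustering of residues
#'
#' Clusters residues purely by CA coordinates, optionally restricted to a
#' selection (e.g. the hotspot residues of a [find_hotspots()] result), with
#' two interchangeable back-ends: HDBSCAN-style density clustering (default)
#' and Markov clustering on a contact graph. Residues outside the selection
#' and unclustered residues are labelled -1; clusters are numbered 0..K-1 by
#' decreasing size (ties by lowest residue index).
#'
#' @param fold A `fold` object.
#' @param selection Which residues to cluster: a `hotspot_result` (its `hot`
#'   flags), a logical mask of length n, a vector of 0-based residue indices,
#'   or `NULL`/`TRUE` for all residues.
#' @param method `"hdbscan"` (default) or `"mcl"`.
#' @param min_cluster_size Minimum cluster size (>= 2), default 5.
#' @param mcl_inflation,mcl_radius MCL inflation exponent and the contact
#'   radius (A) used to build its binary graph.
#' @param allow_single_cluster Permit the density back-end to return the root
#'   cluster containing everything (default `FALSE`).
#' @return A `cluster_labels` object over all residues of `fold`.
#' @export
cluster <- function(fold, selection = NULL,
                    method = c("hdbscan", "mcl"),
                    min_cluster_size = 5,
                    mcl_inflation = 2, mcl_radius = 8,
                    allow_single_cluster = FALSE) {
  stopifnot(inherits(fold, "fold"))
  method <- match.arg(method)
  if (min_cluster_size < 2) stop("value error: min_cluster_size must be >= 2")
  n <- length(fold)

  sel <- if (is.null(selection) || isTRUE(selection)) {
    seq_len(n)
  } else if (inherits(selection, "hotspot_result")) {
    which(selection$hot)
  } else if (is.logical(selection)) {
    if (length(selection) != n) stop("value error: mask length mismatch")
    which(selection)
  } else {
    as.integer(selection) + 1L   # 0-based residue indices
  }
  if (length(sel) == 0L) stop("value error: selection selects no residues")
  if (any(sel < 1L | sel > n)) stop("value error: selection index out of range")

  coords <- ca_coords(fold)[sel, , drop = FALSE]
  if (method == "hdbscan") {
    labs <- hdbscan_points(coords, min_cluster_size = min_cluster_size,
                           allow_single_cluster = allow_single_cluster)
    params <- list(min_cluster_size = min_cluster_size)
  } else {
    d <- as.matrix(stats::dist(coords))
    adj <- (d > 0 & d <= mcl_radius) * 1
    res <- mcl(adj, inflation = mcl_inflation)
    labs <- res$labels
    params <- c(list(min_cluster_size = min_cluster_size,
                     mcl_radius = mcl_radius), res$params)
  }

  full <- rep(-1L, n)
  full[sel] <- labs
  rn <- renumber_labels(full)
  new_cluster_labels(rn$labels, method = method, params = params)
}
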