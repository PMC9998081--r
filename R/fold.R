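# Internal constructor. `atoms` is a data.frame with one row per atom and
# columns: serial, name, element, x, y, z, occupancy, b_factor, chain,
# author_number, insertion_code, res_name, res_index (0-based), is_hetero.
new_fold <- function(atoms, source = "constructed", tracks = list(),
                     subclass = character()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  rownames(atoms) <- NULL
  fold <- structure(
    list(
      atoms = atoms,
      chains = unique(atoms$chain),
      tracks = tracks,
      source = source
    ),
    class = c(subclass, "fold")
  )
  fold
}

#' Number of residues in a structure
#'
#' @param x A `fold` object.
#' @return Integer residue count.
#' @export
length.fold <- function(x) {
  if (nrow(x$atoms) == 0L) return(0L)
  max(x$atoms$res_index) + 1L
}

#' @export
print.fold <- function(x, ...) {
  cat(sprintf("<fold> %d residues, %d atoms, chain(s) %s\n",
              length(x), nrow(x$atoms), paste(x$chains, collapse = ",")))
  if (length(x$tracks)) {
    cat("tracks:", paste(names(x$tracks), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Residue-level view of a structure
#'
#' One row per residue, in linear (0-based `index`) order.
#'
#' @param fold A `fold` object.
#' @return A data.frame with columns `chain`, `index`, `author_number`,
#'   `insertion_code`, `res_name`.
#' @export
residues <- function(fold) {
  stopifnot(inherits(fold, "fold"))
  a <- fold$atoms
  first <- !duplicated(a$res_index)
  data.frame(
    chain = a$chain[first],
    index = a$res_index[first],
    author_number = a$author_number[first],
    insertion_code = a$insertion_code[first],
    res_name = a$res_name[first],
    stringsAsFactors = FALSE
  )
}

# Resolve a path-or-text `source` argument into a character vector of lines.
pdb_lines <- function(source) {
  if (!is.character(source) || length(source) < 1L) {
    stop("input error: `source` must be PDB text or a path to a PDB file")
  }
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE)) {
    if (!file.exists(source)) {
      stop(sprintf("input error: cannot read '%s' (no such file)", source))
    }
    return(readLines(source, warn = FALSE))
  }
  if (length(source) == 1L) return(strsplit(source, "\n", fixed = TRUE)[[1]])
  source
}

# Fixed-width numeric field with a line-numbered parse error.
.pdb_num <- function(lines, lineno, from, to, what) {
  raw <- trimws(substr(lines, from, to))
  val <- suppressWarnings(as.numeric(raw))
  bad <- is.na(val) & raw != ""
  if (any(bad)) {
    stop(sprintf("parse error at line %d: malformed %s field '%s'",
                 lineno[which(bad)[1]], what, raw[which(bad)[1]]))
  }
  val
}

#' Parse a PDB structure
#'
#' Reads fixed-width PDB text (wwPDB v3.3 columns) from a file path or from
#' an in-memory string. Only `ATOM` records of the first `MODEL` enter the
#' residue sequence; `HETATM` records, waters and hydrogens are excluded, and
#' for alternate locations the first-seen conformer wins. Residues are
#' assigned a 0-based linear `index` in file order — the coordinate system
#' used by every downstream operation.
#'
#' @param source Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @return A `fold` object.
#' @export
parse_pdb <- function(source) {
  lines <- pdb_lines(source)
  lineno <- seq_along(lines)

  ## first MODEL only
  mstart <- grep("^MODEL", lines)
  if (length(mstart)) {
    mend <- grep("^ENDMDL", lines)
    last <- if (length(mend)) mend[1] else length(lines)
    keep <- seq(mstart[1], last)
    lines <- lines[keep]
    lineno <- lineno[keep]
  }

  rec <- substr(lines, 1, 6)
  is_atom <- trimws(rec) == "ATOM"
  if (!any(is_atom)) {
    stop("empty-structure error: no ATOM records found")
  }
  lines <- lines[is_atom]
  lineno <- lineno[is_atom]

  name <- trimws(substr(lines, 13, 16))
  element <- trimws(substr(lines, 77, 78))
  ## infer element from the atom name when the element column is blank
  blank <- element == ""
  element[blank] <- substr(gsub("[^A-Za-z]", "", name[blank]), 1, 1)
  element <- toupper(element)

  ## drop hydrogens and deuterium
  heavy <- !(element %in% c("H", "D"))
  lines <- lines[heavy]; lineno <- lineno[heavy]
  name <- name[heavy]; element <- element[heavy]
  if (length(lines) == 0L) {
    stop("empty-structure error: no heavy ATOM records found")
  }

  serial <- .pdb_num(lines, lineno, 7, 11, "serial")
  res_name <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  author_number <- .pdb_num(lines, lineno, 23, 26, "residue number")
  icode <- trimws(substr(lines, 27, 27))
  x <- .pdb_num(lines, lineno, 31, 38, "x coordinate")
  y <- .pdb_num(lines, lineno, 39, 46, "y coordinate")
  z <- .pdb_num(lines, lineno, 47, 54, "z coordinate")
  occ <- .pdb_num(lines, lineno, 55, 60, "occupancy")
  bfac <- .pdb_num(lines, lineno, 61, 66, "b-factor")
  occ[is.na(occ)] <- 1
  bfac[is.na(bfac)] <- 0
  if (any(!is.finite(x) | !is.finite(y) | !is.finite(z))) {
    stop("parse error: non-finite coordinates")
  }

  ## altloc policy: first conformer wins, keyed per residue+atom name
  akey <- paste(chain, author_number, icode, name, sep = "|")
  keep <- !duplicated(akey)

  atoms <- data.frame(
    serial = as.integer(serial[keep]),
    name = name[keep],
    element = element[keep],
    x = x[keep], y = y[keep], z = z[keep],
    occupancy = occ[keep],
    b_factor = bfac[keep],
    chain = chain[keep],
    author_number = as.integer(author_number[keep]),
    insertion_code = icode[keep],
    res_name = res_name[keep],
    is_hetero = FALSE,
    stringsAsFactors = FALSE
  )

  rkey <- paste(atoms$chain, atoms$author_number, atoms$insertion_code,
                sep = "|")
  nr <- nrow(atoms)
  atoms$res_index <- cumsum(c(TRUE, rkey[-1] != rkey[-nr])) - 1L

  src <- if (length(source) == 1L && !grepl("\n", source[1], fixed = TRUE)) {
    source
  } else "<string>"
  new_fold(atoms, source = src)
}

#' Write a structure as PDB text
#'
#' Emits fixed-width `ATOM` records (coordinates with 3 decimals), one `TER`
#' per chain and a final `END`.
#'
#' @param fold A `fold` object.
#' @param path Optional file path; when given the text is also written there.
#' @return The PDB text as a single string (invisibly when `path` is given).
#' @export
write_pdb <- function(fold, path = NULL) {
  stopifnot(inherits(fold, "fold"))
  a <- fold$atoms
  if (nrow(a) == 0L) stop("empty structure: nothing to write")
  nm <- ifelse(nchar(a$name) >= 4, a$name,
               paste0(" ", formatC(a$name, width = -3)))
  rec <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, nm, a$res_name, a$chain, a$author_number,
    ifelse(a$insertion_code == "", " ", a$insertion_code),
    a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
  out <- character(0)
  for (ch in fold$chains) {
    out <- c(out, rec[a$chain == ch], "TER")
  }
  out <- c(out, "END")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' One-letter amino-acid sequence of a chain
#'
#' Strict 3-to-1 mapping of the 20 standard residues; anything else
#' (e.g. MSE) maps to `"X"`.
#'
#' @param fold A `fold` object.
#' @param chain Chain identifier.
#' @return A single string.
#' @export
fold_sequence <- function(fold, chain) {
  stopifnot(inherits(fold, "fold"))
  if (!chain %in% fold$chains) {
    stop(sprintf("key error: chain '%s' not present (have: %s)",
                 chain, paste(fold$chains, collapse = ",")))
  }
  r <- residues(fold)
  r <- r[r$chain == chain, , drop = FALSE]
  one <- .aa3to1[r$res_name]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Remove chains from a complex
#'
#' Drops the listed chains; surviving residues keep their relative order and
#' are re-indexed 0..n-1. Feature tracks are dropped because their length no
#' longer matches.
#'
#' @param fold A `fold` object (typically a multi-chain complex).
#' @param chain_ids Chains to remove, as a single string of chain letters
#'   (e.g. `"AB"`) or a character vector.
#' @return A `fold` without the listed chains.
#' @export
remove_chains <- function(fold, chain_ids) {
  stopifnot(inherits(fold, "fold"))
  if (length(chain_ids) == 1L && nchar(chain_ids) != 1L) {
    chain_ids <- strsplit(chain_ids, "")[[1]]
  }
  chain_ids <- chain_ids[chain_ids != ""]
  if (length(chain_ids) == 0L) return(fold)
  missing <- setdiff(chain_ids, fold$chains)
  if (length(missing)) {
    stop(sprintf("key error: unknown chain(s): %s",
                 paste(missing, collapse = ",")))
  }
  a <- fold$atoms[!(fold$atoms$chain %in% chain_ids), , drop = FALSE]
  if (nrow(a) == 0L) stop("removing all chains leaves an empty structure")
  rkey <- paste(a$chain, a$author_number, a$insertion_code, sep = "|")
  nr <- nrow(a)
  a$res_index <- cumsum(c(TRUE, rkey[-1] != rkey[-nr])) - 1L
  new_fold(a, source = fold$source)
}

#' @rdname remove_chains
#' @param e1,e2 A `fold` and a chain string, for `cx - "AB"` syntax.
#' @export
`-.fold` <- function(e1, e2) remove_chains(e1, e2)

#' C-alpha coordinate matrix
#'
#' @param fold A `fold` object.
#' @param fallback Either `"error"` (default: a residue without a CA atom is
#'   an error) or `"first_atom"` (use the residue's first atom instead).
#' @return An n x 3 numeric matrix, row i = residue i's CA position (A).
#' @export
ca_coords <- function(fold, fallback = c("error", "first_atom")) {
  stopifnot(inherits(fold, "fold"))
  fallback <- match.arg(fallback)
  a <- fold$atoms
  n <- length(fold)
  out <- matrix(NA_real_, n, 3)
  ca <- a[a$name == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$res_index), , drop = FALSE]
  out[ca$res_index + 1L, ] <- cbind(ca$x, ca$y, ca$z)
  miss <- which(is.na(out[, 1])) - 1L
  if (length(miss)) {
    if (fallback == "error") {
      stop(sprintf("residue at index %d has no CA atom (set fallback = 'first_atom' to use its first atom)",
                   miss[1]))
    }
    fa <- a[!duplicated(a$res_index), , drop = FALSE]
    fa <- fa[fa$res_index %in% miss, , drop = FALSE]
    out[fa$res_index + 1L, ] <- cbind(fa$x, fa$y, fa$z)
  }
  out
}

#' Residue-residue distance matrix
#'
#' @param fold A `fold` object.
#' @param mode `"ca"` for CA-CA Euclidean distances, `"min_heavy"` for the
#'   minimum over all heavy-atom (non-hydrogen) pairs.
#' @return Symmetric n x n matrix in Angstrom with zero diagonal.
#' @export
distance_matrix <- function(fold, mode = c("ca", "min_heavy")) {
  stopifnot(inherits(fold, "fold"))
  mode <- match.arg(mode)
  n <- length(fold)
  if (n == 0L) stop("empty structure")
  if (mode == "ca") {
    return(unname(as.matrix(stats::dist(ca_coords(fold)))))
  }
  a <- fold$atoms[!(fold$atoms$element %in% c("H", "D")), , drop = FALSE]
  D <- as.matrix(stats::dist(cbind(a$x, a$y, a$z)))
  idx <- split(seq_len(nrow(a)), factor(a$res_index, levels = 0:(n - 1)))
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- min(D[idx[[i]], idx[[j]]])
      out[i, j] <- m
      out[j, i] <- m
    }
  }
  dimnames(out) <- NULL
  out
}

#' Per-residue distance from one chain to another
#'
#' For each residue of `query_chain`, the minimum heavy-atom distance to any
#' atom of `target_chain` — e.g. the distance to a binding partner in a
#' complex.
#'
#' @param fold A multi-chain `fold`.
#' @param query_chain,target_chain Distinct chain identifiers.
#' @return Numeric vector over the residues of `query_chain`, in their linear
#'   order.
#' @export
distance_to_chain <- function(fold, query_chain, target_chain) {
  stopifnot(inherits(fold, "fold"))
  for (ch in c(query_chain, target_chain)) {
    if (!ch %in% fold$chains) {
      stop(sprintf("key error: chain '%s' not present", ch))
    }
  }
  if (identical(query_chain, target_chain)) {
    stop("query and target chain must be distinct")
  }
  a <- fold$atoms[!(fold$atoms$element %in% c("H", "D")), , drop = FALSE]
  qa <- a[a$chain == query_chain, , drop = FALSE]
  ta <- as.matrix(a[a$chain == target_chain, c("x", "y", "z")])
  ridx <- sort(unique(qa$res_index))
  vapply(ridx, function(ri) {
    qm <- as.matrix(qa[qa$res_index == ri, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(qm^2), rowSums(ta^2), "+") - 2 * qm %*% t(ta)
    sqrt(max(min(d2), 0))
  }, numeric(1))
}

#' Interface residues between two chains
#'
#' Residues of `chain_a` whose minimum heavy-atom distance to `chain_b` is at
#' most `cutoff` — contact residues at a protein-protein interface.
#'
#' @param fold A multi-chain `fold`.
#' @param chain_a,chain_b Distinct chain identifiers.
#' @param cutoff Contact cutoff in Angstrom (> 0).
#' @return Integer vector of 0-based residue indices (within the fold's
#'   linear order) of the contacting residues of `chain_a`.
#' @export
interface_residues <- function(fold, chain_a, chain_b, cutoff = 5) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  d <- distance_to_chain(fold, chain_a, chain_b)
  ridx <- sort(unique(fold$atoms$res_index[fold$atoms$chain == chain_a]))
  ridx[d <= cutoff]
}

#' Load an AlphaFold-predicted model
#'
#' Parses a PDB file whose B-factor column stores the per-residue pLDDT
#' confidence (0-100) and attaches it as the `plddt` track. Values outside
#' [0, 100] are kept but trigger a warning and are flagged in the object.
#'
#' @param source Path or PDB text, as for [parse_pdb()].
#' @return A `fold` of subclass `alphafold` with elements `plddt` (numeric
#'   vector) and `plddt_flagged` (logical).
#' @export
load_alphafold <- function(source) {
  fold <- parse_pdb(source)
  a <- fold$atoms
  first <- !duplicated(a$res_index)
  plddt <- a$b_factor[first]
  flagged <- any(plddt < 0 | plddt > 100)
  if (flagged) {
    warning("pLDDT values outside [0, 100] found; kept as-is and flagged")
  }
  fold$plddt <- plddt
  fold$plddt_flagged <- flagged
  fold$tracks$plddt <- plddt
  class(fold) <- c("alphafold", class(fold))
  fold
}
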