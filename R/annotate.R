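#' Attach a named per-residue feature track
#'
#' Stores (or overwrites) a length-n numeric track on the structure. A
#' [find_hotspots()] result contributes its hot flags as 0/1; a [cluster()]
#' result contributes its integer labels; logical vectors are stored as 0/1.
#'
#' @param fold A `fold` object.
#' @param name Track name.
#' @param values Per-residue values of length `length(fold)`, or a
#'   `hotspot_result` / `cluster_labels` object.
#' @return The updated `fold`.
#' @export
annotate <- function(fold, name, values) {
  stopifnot(inherits(fold, "fold"), is.character(name), length(name) == 1L)
  if (inherits(values, "hotspot_result")) values <- as.integer(values$hot)
  if (inherits(values, "cluster_labels")) values <- values$labels
  if (is.logical(values)) values <- as.integer(values)
  n <- length(fold)
  if (length(values) != n) {
    stop(sprintf("value error: track '%s' has length %d but the fold has %d residues",
                 name, length(values), n))
  }
  fold$tracks[[name]] <- as.numeric(values)
  fold
}

#' Attach several tracks at once
#'
#' @param fold A `fold` object.
#' @param tracks Named list of per-residue vectors (or hotspot/cluster
#'   results), e.g. `list(positive = ..., hotspots = ..., clusters = ...)`.
#' @return The updated `fold`.
#' @export
annotate_many <- function(fold, tracks) {
  stopifnot(is.list(tracks), !is.null(names(tracks)), all(names(tracks) != ""))
  for (nm in names(tracks)) fold <- annotate(fold, nm, tracks[[nm]])
  fold
}

#' Export annotations as a tidy per-residue table
#'
#' One row per residue in linear order; fixed columns `chain`,
#' `residue_index` (0-based), `author_number`, `res_name`, then one column
#' per track in insertion order.
#'
#' @param fold A `fold` object.
#' @return A data.frame with `length(fold)` rows.
#' @export
to_table <- function(fold) {
  stopifnot(inherits(fold, "fold"))
  r <- residues(fold)
  out <- data.frame(
    chain = r$chain,
    residue_index = r$index,
    author_number = r$author_number,
    res_name = r$res_name,
    stringsAsFactors = FALSE
  )
  for (nm in names(fold$tracks)) out[[nm]] <- fold$tracks[[nm]]
  out
}

#' Write an annotation table to delimited text
#'
#' @param x A `fold` (converted with [to_table()]) or a data.frame.
#' @param path Output path.
#' @param sep Field separator; tab (default) or `","`.
#' @param comments Optional character vector of `# key=value` provenance
#'   lines written before the header.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path, sep = "\t", comments = NULL) {
  tab <- if (inherits(x, "fold")) to_table(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(tab, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a delimited annotation table
#'
#' Counterpart of [write_annotations()]; `#` comment lines are skipped.
#'
#' @param path Input path.
#' @param sep Field separator.
#' @return A data.frame.
#' @export
read_annotations <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop(sprintf("input error: cannot read '%s' (no such file)", path))
  }
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
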