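# Built-in palette table. Ordered hex lists; continuous tracks are min-max
# normalized then linearly interpolated through the list, so a binary track
# resolves to exactly the two endpoint colors.
.set2 <- c("#66C2A5", "#FC8D62", "#8DA0CB", "#E78AC3",
           "#A6D854", "#FFD92F", "#E5C494", "#B3B3B3")
.palettes <- list(
  binary = c("#FFFFFF", "#000000"),
  greys = c("#F7F7F7", "#252525"),
  viridis = c("#440154", "#21918C", "#FDE725"),
  rdbu = c("#B2182B", "#F7F7F7", "#2166AC"),
  Set2 = .set2,
  Set2_r = rev(.set2)
)

#' Create an empty layered scene
#'
#' Grammar-of-graphics style scene bound to a structure: a grid of panels of
#' fixed pixel size onto which geom layers are added with [geom_ribbon()],
#' [geom_sphere()] and [geom_surface()], then compiled with [render_scene()].
#'
#' @param fold A `fold` object.
#' @param panel_size `c(width, height)` in pixels.
#' @param grid `c(rows, cols)` panel grid; panels are addressed 0-based.
#' @param linked Should viewers synchronize cameras across panels? Carried as
#'   metadata in the rendered document.
#' @return A `scene` object.
#' @export
scene_layout <- function(fold, panel_size = c(200, 200), grid = c(1, 1),
                         linked = FALSE) {
  stopifnot(inherits(fold, "fold"))
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) {
    stop("value error: grid must be two integers >= 1")
  }
  if (length(panel_size) != 2L || any(panel_size <= 0)) {
    stop("value error: panel_size must be two positive numbers")
  }
  structure(
    list(fold = fold, grid = grid, panel_size = as.numeric(panel_size),
         linked = isTRUE(linked), layers = list()),
    class = "scene")
}

#' Select residues/atoms for a layer
#'
#' A declarative (lazily resolved) subset of a structure: by 0-based residue
#' indices, by atom names (elements of the rendering, e.g. `"CA"`), and/or by
#' chain. `NULL` means no restriction.
#'
#' @param x A `scene` or `fold` (only used for early chain validation).
#' @param residues 0-based residue indices, a logical mask, or a 0/1 feature
#'   vector (positions with value 1 are selected).
#' @param elements Atom names to keep.
#' @param chain Chain identifier to keep.
#' @return A `selection` object.
#' @export
scene_select <- function(x, residues = NULL, elements = NULL, chain = NULL) {
  fold <- if (inherits(x, "scene")) x$fold else x
  stopifnot(inherits(fold, "fold"))
  if (!is.null(chain) && !chain %in% fold$chains) {
    stop(sprintf("key error: chain '%s' not present", chain))
  }
  if (!is.null(residues)) {
    if (is.logical(residues) ||
        (length(residues) == length(fold) &&
         all(residues %in% c(0, 1)) && length(fold) > 1)) {
      residues <- which(as.logical(residues)) - 1L
    }
    residues <- as.integer(residues)
  }
  structure(list(residues = residues, elements = elements, chain = chain),
            class = "selection")
}

.check_layer_aes <- function(color, track, palette, scene) {
  has_color <- !is.null(color)
  has_track <- !is.null(track)
  if (has_color == has_track) {
    stop("value error: a layer needs exactly one of `color` or `track`+`palette`")
  }
  if (has_track) {
    if (is.null(palette)) {
      stop("value error: a track-colored layer needs a `palette`")
    }
    if (!palette %in% names(.palettes)) {
      stop(sprintf("value error: unknown palette '%s' (known: %s)",
                   palette, paste(names(.palettes), collapse = ", ")))
    }
    if (is.null(scene$fold$tracks[[track]])) {
      stop(sprintf("value error: no track named '%s' on the structure", track))
    }
  }
  invisible(NULL)
}

.add_layer <- function(scene, kind, selection, color, track, palette, panel) {
  stopifnot(inherits(scene, "scene"))
  .check_layer_aes(color, track, palette, scene)
  panel <- as.integer(panel)
  if (length(panel) != 2L || any(panel < 0L) ||
      panel[1] >= scene$grid[1] || panel[2] >= scene$grid[2]) {
    stop(sprintf("value error: panel (%s) outside 0-based grid (%d, %d)",
                 paste(panel, collapse = ", "),
                 scene$grid[1], scene$grid[2]))
  }
  if (!is.null(selection) && !inherits(selection, "selection")) {
    stop("value error: `selection` must come from scene_select()")
  }
  scene$layers[[length(scene$layers) + 1L]] <- list(
    kind = kind, selection = selection, color = color,
    track = track, palette = palette, panel = panel)
  scene
}

#' Add geom layers to a scene
#'
#' Layers render in insertion order (later over earlier) in their panel
#' (default `(0, 0)`). Each layer is colored either by a fixed `color` or by
#' a `track` resolved through a named `palette` — exactly one of the two.
#'
#' @param scene A [scene_layout()] object.
#' @param selection Optional [scene_select()] restriction.
#' @param color Fixed color (hex string or color name).
#' @param track Track name to color by.
#' @param palette Palette name (`"binary"`, `"Set2"`, `"Set2_r"`, `"greys"`,
#'   `"viridis"`, `"rdbu"`).
#' @param panel 0-based `c(row, col)` panel address.
#' @return The updated `scene`.
#' @export
geom_ribbon <- function(scene, selection = NULL, color = NULL, track = NULL,
                        palette = NULL, panel = c(0, 0)) {
  .add_layer(scene, "ribbon", selection, color, track, palette, panel)
}

#' @rdname geom_ribbon
#' @export
geom_sphere <- function(scene, selection = NULL, color = NULL, track = NULL,
                        palette = NULL, panel = c(0, 0)) {
  .add_layer(scene, "sphere", selection, color, track, palette, panel)
}

#' @rdname geom_ribbon
#' @export
geom_surface <- function(scene, track = NULL, palette = NULL, color = NULL,
                         selection = NULL, panel = c(0, 0)) {
  .add_layer(scene, "surface", selection, color, track, palette, panel)
}

# resolve a selection against a fold -> integer vector of atom row indices
.resolve_selection <- function(fold, sel) {
  a <- fold$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel)) {
    if (!is.null(sel$chain)) {
      if (!sel$chain %in% fold$chains) {
        stop(sprintf("key error: chain '%s' not present", sel$chain))
      }
      keep <- keep & a$chain == sel$chain
    }
    if (!is.null(sel$residues)) keep <- keep & a$res_index %in% sel$residues
    if (!is.null(sel$elements)) keep <- keep & a$name %in% sel$elements
  }
  which(keep)
}

# per-residue colors for a track through a palette (min-max + linear ramp)
.track_colors <- function(values, palette) {
  pal <- .palettes[[palette]]
  rng <- range(values)
  t <- if (diff(rng) == 0) rep(0, length(values)) else {
    (values - rng[1]) / diff(rng)
  }
  ramp <- grDevices::colorRampPalette(pal)(256)
  ramp[1L + round(t * 255)]
}

#' Compile a scene to its JSON document
#'
#' Produces the viewer-neutral scene description: schema version, panel grid,
#' the structure as embedded PDB text, and every layer fully resolved —
#' concrete atom serials for its selection and, for track-colored layers,
#' concrete per-residue hex colors. Pure and deterministic: identical input
#' yields byte-identical output.
#'
#' @param scene A `scene` with at least one layer.
#' @param path Optional output path for the JSON text.
#' @return The JSON document as a single string (invisibly when `path` is
#'   given).
#' @export
render_scene <- function(scene, path = NULL) {
  stopifnot(inherits(scene, "scene"))
  if (length(scene$layers) == 0L) stop("value error: scene has no layers")
  fold <- scene$fold

  panels <- list()
  for (r in 0:(scene$grid[1] - 1L)) {
    for (co in 0:(scene$grid[2] - 1L)) {
      panels[[length(panels) + 1L]] <- list(row = r, col = co)
    }
  }

  layers <- lapply(scene$layers, function(ly) {
    rows <- .resolve_selection(fold, ly$selection)
    out <- list(
      kind = ly$kind,
      panel = I(ly$panel),
      atom_serials = I(fold$atoms$serial[rows])
    )
    if (!is.null(ly$color)) {
      out$color <- ly$color
    } else {
      out$track <- ly$track
      out$palette <- ly$palette
      out$residue_colors <- I(.track_colors(fold$tracks[[ly$track]],
                                            ly$palette))
    }
    out
  })

  doc <- list(
    scene_version = 1L,
    grid = I(scene$grid),
    panel_size = I(scene$panel_size),
    linked = scene$linked,
    pdb = write_pdb(fold),
    panels = panels,
    layers = layers
  )
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 8))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a per-residue attribute file for external viewers
#'
#' ChimeraX `defattr`-style text: a header `attribute: <name>` followed by
#' one record per residue, `\t/<chain>:<author_number><icode>\t<value>`,
#' values at full precision.
#'
#' @param fold A `fold` object.
#' @param track Name of an attached track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(fold, track, path) {
  stopifnot(inherits(fold, "fold"))
  v <- fold$tracks[[track]]
  if (is.null(v)) stop(sprintf("value error: no track named '%s'", track))
  r <- residues(fold)
  lines <- c(
    sprintf("attribute: %s", track),
    sprintf("\t/%s:%d%s\t%s", r$chain, r$author_number, r$insertion_code,
            sprintf("%.17g", v))
  )
  writeLines(lines, path)
  invisible(path)
}
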