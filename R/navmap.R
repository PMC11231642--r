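# Navigation maps: small 3-D grids of cells carrying object features,
# operational tags, and a start marker. Cells are stored sparsely, keyed by
# their "x,y,z" coordinate string; coordinates are 0-based.

coord_key <- function(coord) paste(as.integer(coord), collapse = ",")

key_coord <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

TAG_KINDS <- c("action-word", "all-marker", "back-marker", "visit-order")

#' Create a tag
#'
#' Tags are the operational annotations placed on navigation-map cells:
#' action words from an instruction, the `all`/`back` destination markers
#' set by [parse_goto()], and the integer visit-order tags (`<1>`, `<2>`,
#' ..., `<0>` for the start) written by [small_plan()].
#'
#' @param kind One of `"action-word"`, `"all-marker"`, `"back-marker"`,
#'   `"visit-order"`.
#' @param value Tag payload: a string for the word kinds, a non-negative
#'   integer for `"visit-order"`. The marker kinds default to `"all"` and
#'   `"back"`.
#' @return A `nav_tag` object.
#' @export
nav_tag <- function(kind, value = NULL) {
  kind <- match.arg(kind, TAG_KINDS)
  if (is.null(value)) {
    value <- switch(kind,
      "all-marker" = "all",
      "back-marker" = "back",
      stop("tag kind '", kind, "' needs an explicit value", call. = FALSE)
    )
  }
  if (kind == "visit-order") {
    value <- as.integer(value)
    if (is.na(value) || value < 0L) {
      stop("visit-order tags carry a non-negative integer", call. = FALSE)
    }
  } else {
    value <- as.character(value)
  }
  structure(list(kind = kind, value = value), class = "nav_tag")
}

new_cell <- function(features = character(), links = list(),
                     tags = list(), is_start = FALSE) {
  list(features = as.character(features), links = links,
       tags = tags, is_start = isTRUE(is_start))
}

#' Build a navigation map from object placements
#'
#' Constructs the grid-of-cells representation of a sensory scene: one
#' featured cell per object plus a cell carrying the start marker. The grid
#' is `dims[1] x dims[2] x dims[3]` with 0-based coordinates; the default
#' matches the 6x6 single-layer maps used throughout the simulations.
#'
#' @param dims Integer triple of grid extents.
#' @param objects List of `list(coord = c(x, y, z), features = c(...))`
#'   placements.
#' @param start Coordinate of the starting cell.
#' @param map_id Integer identifier for cross-map links.
#' @return A `nav_map` object.
#' @examples
#' m <- nav_map(objects = list(
#'   list(coord = c(2, 2, 0), features = c("sphere", "white"))),
#'   start = c(0, 0, 0))
#' @export
nav_map <- function(dims = c(6L, 6L, 1L), objects = list(),
                    start = c(0L, 0L, 0L), map_id = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  check_bounds <- function(coord) {
    coord <- as.integer(coord)
    if (length(coord) != 3L || any(is.na(coord)) ||
        any(coord < 0L) || any(coord >= dims)) {
      stop("coordinate (", paste(coord, collapse = ","),
           ") is outside the map dimensions", call. = FALSE)
    }
    coord
  }
  cells <- list()
  for (obj in objects) {
    coord <- check_bounds(obj$coord)
    key <- coord_key(coord)
    if (!is.null(cells[[key]])) {
      stop("duplicate object coordinate (", key, ")", call. = FALSE)
    }
    cells[[key]] <- new_cell(features = obj$features)
  }
  start <- check_bounds(start)
  skey <- coord_key(start)
  if (!is.null(cells[[skey]])) {
    stop("start coincides with an object cell at (", skey, ")",
         call. = FALSE)
  }
  cells[[skey]] <- new_cell(is_start = TRUE)
  structure(list(dims = dims, cells = cells, map_id = as.integer(map_id)),
            class = "nav_map")
}

#' @export
print.nav_map <- function(x, ...) {
  n_obj <- sum(vapply(x$cells, function(c) length(c$features) > 0L,
                      logical(1)))
  cat("<nav_map ", paste(x$dims, collapse = "x"), ": ", n_obj,
      " object cell(s), ", length(x$cells), " occupied>\n", sep = "")
  for (key in map_scan_order(x)) {
    cell <- x$cells[[key]]
    tags <- vapply(cell$tags, function(t) paste0("<", t$value, ">"),
                   character(1))
    cat("  (", key, ") ", paste(cell$features, collapse = " "),
        if (cell$is_start) " [start]" else "",
        if (length(tags)) paste0(" ", paste(tags, collapse = " ")) else "",
        "\n", sep = "")
  }
  invisible(x)
}

# Row-major scan order (x fastest, then y, then z); used wherever a
# deterministic cell ordering is required.
map_scan_order <- function(map) {
  keys <- names(map$cells)
  if (length(keys) == 0L) return(character())
  coords <- t(vapply(keys, key_coord, integer(3)))
  keys[order(coords[, 3], coords[, 2], coords[, 1])]
}

start_key <- function(map) {
  for (key in names(map$cells)) {
    if (isTRUE(map$cells[[key]]$is_start)) return(key)
  }
  NULL
}

object_keys <- function(map) {
  keys <- map_scan_order(map)
  keys[vapply(keys, function(k) length(map$cells[[k]]$features) > 0L,
              logical(1))]
}

tag_identity <- function(tag) paste(tag$kind, tag$value, sep = "\r")

# Tags are unique per cell: re-adding an identical tag is a no-op.
add_tag <- function(map, key, tag) {
  cell <- map$cells[[key]]
  if (is.null(cell)) stop("no cell at (", key, ")", call. = FALSE)
  have <- vapply(cell$tags, tag_identity, character(1))
  if (!(tag_identity(tag) %in% have)) {
    cell$tags <- c(cell$tags, list(tag))
    map$cells[[key]] <- cell
  }
  map
}

cell_tags <- function(map, key, kind = NULL) {
  tags <- map$cells[[key]]$tags
  if (is.null(kind)) return(tags)
  tags[vapply(tags, function(t) t$kind == kind, logical(1))]
}

keys_with_tag <- function(map, kind) {
  keys <- map_scan_order(map)
  keys[vapply(keys, function(k) length(cell_tags(map, k, kind)) > 0L,
              logical(1))]
}

drop_tags <- function(map, kinds) {
  for (key in names(map$cells)) {
    tags <- map$cells[[key]]$tags
    keep <- vapply(tags, function(t) !(t$kind %in% kinds), logical(1))
    map$cells[[key]]$tags <- tags[keep]
  }
  map
}

#' Copy a navigation map
#'
#' Returns a deep, independent copy, optionally dropping action-word tags.
#' This is the operation used when a tagged map is broadcast into the module
#' bank: the destination markers travel with the copy, the instruction words
#' do not.
#'
#' @param map A `nav_map`.
#' @param strip_action_words Drop all action-word tags from the copy.
#' @return A new `nav_map`.
#' @export
copy_map <- function(map, strip_action_words = FALSE) {
  out <- map  # R list semantics: modification never touches the original
  if (strip_action_words) out <- drop_tags(out, "action-word")
  out
}

#' Serialize a navigation map to JSON
#'
#' Schema: `dims` (length-3 array), `map_id`, and `cells` keyed `"x,y,z"`,
#' each with `features` (string array), `links` (`{map_id, coord}` objects),
#' `tags` (`{kind, value}` objects) and `is_start`.
#'
#' @param map A `nav_map`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
map_to_json <- function(map, path = NULL) {
  cells <- lapply(map$cells, function(cell) {
    list(
      features = as.list(cell$features),
      links = lapply(cell$links, function(l)
        list(map_id = l$map_id, coord = as.list(l$coord))),
      tags = lapply(cell$tags, function(t)
        list(kind = t$kind, value = t$value)),
      is_start = cell$is_start
    )
  })
  obj <- list(dims = as.list(map$dims), map_id = map$map_id, cells = cells)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Read a navigation map from JSON
#'
#' Inverse of [map_to_json()].
#'
#' @param x JSON string or path to a JSON file.
#' @return A `nav_map`.
#' @export
map_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  cells <- lapply(obj$cells, function(cell) {
    tags <- lapply(cell$tags, function(t) nav_tag(t$kind, t$value))
    links <- lapply(cell$links, function(l)
      list(map_id = as.integer(l$map_id), coord = unlist(l$coord)))
    new_cell(features = unlist(cell$features) %||% character(),
             links = links, tags = tags, is_start = isTRUE(cell$is_start))
  })
  structure(list(dims = as.integer(unlist(obj$dims)),
                 cells = cells,
                 map_id = as.integer(obj$map_id)),
            class = "nav_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
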