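# Symmetric pairwise distance tables. The planner treats entries as
# unitless magnitudes; `units` is a free-text annotation only.

#' Create a symmetric distance table
#'
#' @param d Square numeric matrix of pairwise distances: symmetric, zero
#'   diagonal, non-negative entries. Asymmetric input is rejected outright.
#' @param labels Location identifiers, one per row; defaults to the matrix
#'   dimnames or `"1"..."n"`. Row/column order defines the location index;
#'   index 1 is conventionally the start/home location.
#' @param units Free-text unit annotation (ignored by planning).
#' @return A `distance_table`.
#' @export
distance_table <- function(d, labels = NULL, units = "") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (!is.numeric(d) || anyNA(d)) {
    stop("distance matrix must be numeric with no missing values",
         call. = FALSE)
  }
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(d != t(d))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (is.null(labels)) labels <- rownames(d) %||% as.character(seq_len(nrow(d)))
  labels <- as.character(labels)
  if (length(labels) != nrow(d) || anyDuplicated(labels)) {
    stop("labels must be unique, one per location", call. = FALSE)
  }
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, d = d, units = units),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("<distance_table: ", length(x$labels), " locations",
      if (nzchar(x$units)) paste0(", units: ", x$units) else "",
      ">\n", sep = "")
  print(x$d)
  invisible(x)
}

#' Number of locations in a distance table
#' @param dt A `distance_table`.
#' @export
n_locations <- function(dt) length(dt$labels)

dt_dist <- function(dt, a, b) dt$d[a, b]

#' Read a distance matrix from CSV or TSV
#'
#' Accepts a square numeric matrix with an optional first header row of
#' location labels. Row/column order defines the location indices; index 1
#' is the home location. Asymmetric input is rejected with no tolerance.
#'
#' @param path File path.
#' @param format `"csv"` or `"tsv"`.
#' @param units Unit annotation to attach.
#' @return A `distance_table`.
#' @export
read_distance_matrix <- function(path, format = c("csv", "tsv"),
                                 units = "") {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  raw <- read.csv(path, header = has_header, sep = sep,
                  check.names = FALSE)
  d <- as.matrix(raw)
  if (!is.numeric(d)) stop("non-numeric entries in distance matrix",
                           call. = FALSE)
  labels <- if (has_header) colnames(raw) else NULL
  rownames(d) <- NULL
  distance_table(d, labels = labels, units = units)
}

#' Write a distance matrix to CSV or TSV
#'
#' Inverse of [read_distance_matrix()]; a header row of labels is always
#' written.
#'
#' @param dt A `distance_table`.
#' @param path File path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_distance_matrix <- function(dt, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(dt$labels, collapse = sep), con)
  write.table(dt$d, con, sep = sep, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Generate a random symmetric distance table
#'
#' Seeded fixture generator emulating a city-table input: integer distances
#' drawn uniformly from `distance_range`, symmetrized, zero diagonal.
#' With `metric_repair`, all-pairs shortest paths replace direct distances
#' so that every triangle inequality holds.
#'
#' @param n Number of locations (at least 3).
#' @param distance_range Integer `(low, high)` with `low >= 1`.
#' @param metric_repair Enforce the triangle inequality.
#' @param seed Optional integer seed; identical specs reproduce identical
#'   tables.
#' @param labels Optional location labels.
#' @return A `distance_table`.
#' @export
random_distance_table <- function(n, distance_range = c(50L, 2000L),
                                  metric_repair = FALSE, seed = NULL,
                                  labels = NULL) {
  stopifnot(n >= 3L, length(distance_range) == 2L,
            distance_range[1] >= 1L,
            distance_range[2] >= distance_range[1])
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(0, n, n)
  upper <- upper.tri(d)
  d[upper] <- sample(seq.int(distance_range[1], distance_range[2]),
                     sum(upper), replace = TRUE)
  d <- d + t(d)
  if (metric_repair) {
    # Floyd-Warshall: shortest-path closure preserves symmetry and
    # integrality while enforcing d[i,j] <= d[i,k] + d[k,j].
    for (k in seq_len(n)) {
      via <- outer(d[, k], d[k, ], `+`)
      d <- pmin(d, via)
    }
    diag(d) <- 0
  }
  distance_table(d, labels = labels)
}

#' The 13-city distance table
#'
#' The symmetric inter-city mileage matrix (13 cities, index 1 the home
#' city) used throughout the comparative planning experiments; the instance
#' originates from the Google OR-Tools routing examples. Its exact optimal
#' tour is 7,293 miles and the plain nearest-neighbour tour from home is
#' 8,131 miles.
#'
#' @return A `distance_table` with 13 locations, miles.
#' @export
cities13 <- function() {
  path <- system.file("extdata", "cities13.csv", package = "navbank",
                      mustWork = TRUE)
  read_distance_matrix(path, format = "csv", units = "miles")
}

#' The three-object toy scene
#'
#' The worked navigation example: a start cell at (0,0,0), a white sphere at
#' (2,2,0), a black sphere at (3,0,0) and a white block at (4,2,0), with
#' pairwise distances in cm (start-ws 25, start-bs 31, start-wb 42,
#' ws-bs 22, ws-wb 24, bs-wb 20). Plain nearest-neighbour yields a 109 cm
#' tour; the optimal tour is 100 cm.
#'
#' @return `list(map = <nav_map>, distances = <distance_table>)`.
#' @export
toy_scene <- function() {
  map <- nav_map(
    dims = c(6L, 6L, 1L),
    objects = list(
      list(coord = c(2L, 2L, 0L), features = c("sphere", "white")),
      list(coord = c(3L, 0L, 0L), features = c("sphere", "black")),
      list(coord = c(4L, 2L, 0L), features = c("block", "white"))
    ),
    start = c(0L, 0L, 0L)
  )
  labels <- c("0,0,0", "2,2,0", "3,0,0", "4,2,0")
  d <- matrix(0, 4, 4, dimnames = list(labels, labels))
  d["0,0,0", "2,2,0"] <- d["2,2,0", "0,0,0"] <- 25
  d["0,0,0", "3,0,0"] <- d["3,0,0", "0,0,0"] <- 31
  d["0,0,0", "4,2,0"] <- d["4,2,0", "0,0,0"] <- 42
  d["2,2,0", "3,0,0"] <- d["3,0,0", "2,2,0"] <- 22
  d["2,2,0", "4,2,0"] <- d["4,2,0", "2,2,0"] <- 24
  d["3,0,0", "4,2,0"] <- d["4,2,0", "3,0,0"] <- 20
  list(map = map, distances = distance_table(d, units = "cm"))
}
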