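# Shared fixtures and independent oracles. The tour enumerator below is
# deliberately naive (full permutation scan) so that it can serve as an
# oracle for the Held-Karp implementation and the planner invariants.

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

tour_length <- function(dt, path_idx) {
  sum(dt$d[cbind(path_idx[-length(path_idx)], path_idx[-1L])])
}

# Exhaustive shortest closed tour; feasible to ~8 locations.
exhaustive_shortest <- function(dt, start = 1L) {
  ids <- setdiff(seq_len(n_locations(dt)), start)
  min(vapply(all_perms(ids),
             function(p) tour_length(dt, c(start, p, start)),
             numeric(1)))
}

# All distinct closed-tour lengths (each direction counted; the symmetric
# table makes reversals equal).
all_tour_totals <- function(dt, start = 1L) {
  ids <- setdiff(seq_len(n_locations(dt)), start)
  vapply(all_perms(ids),
         function(p) tour_length(dt, c(start, p, start)), numeric(1))
}

# Random grid scene with a matching coordinate-keyed distance table.
random_scene <- function(n_objects, dims = c(6L, 6L, 1L), seed = 1L) {
  set.seed(seed)
  n_cells <- prod(dims)
  stopifnot(n_objects + 1L <= n_cells)
  picks <- sample.int(n_cells, n_objects + 1L) - 1L
  coords <- cbind(picks %% dims[1],
                  (picks %/% dims[1]) %% dims[2],
                  picks %/% (dims[1] * dims[2]))
  feats <- c("sphere", "block", "cone", "cylinder", "black", "white",
             "red", "blue")
  objects <- lapply(seq_len(n_objects), function(i) {
    list(coord = coords[i, ], features = sample(feats, 2L))
  })
  start <- coords[n_objects + 1L, ]
  map <- nav_map(dims = dims, objects = objects, start = start)
  labels <- c(apply(coords[seq_len(n_objects), , drop = FALSE], 1,
                    paste, collapse = ","),
              paste(start, collapse = ","))
  labels <- sort(labels)
  dt <- random_distance_table(length(labels), c(5L, 60L),
                              labels = labels)
  list(map = map, distances = dt, n_objects = n_objects)
}

toy_forced_draws <- c(0.55, 0.95, 0)  # forces the 100 cm alternative route
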