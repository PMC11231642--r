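# Exact shortest-tour oracle. Held-Karp dynamic programming over subsets:
# O(2^m * m^2) for m = n - 1 non-start locations, practical to ~15
# locations. Because the tables are symmetric, a cycle and its reversal
# have equal length; the DP returns one representative.

#' Exact shortest closed tour (Held-Karp)
#'
#' Computes the exact minimum-length Hamiltonian cycle through all
#' locations, starting and ending at `start`. On the 13-city table the
#' optimum is 7,293 miles.
#'
#' @param dt A `distance_table` with at most 16 locations.
#' @param start 1-based index (or label) of the start location.
#' @return `list(total = <number>, order = <labels in visit order,
#'   excluding the start at either end>)`.
#' @export
brute_force_shortest <- function(dt, start = 1L) {
  stopifnot(inherits(dt, "distance_table"))
  n <- n_locations(dt)
  if (is.character(start)) start <- match(start, dt$labels)
  stopifnot(!is.na(start), start >= 1L, start <= n)
  if (n > 16L) {
    stop("exact oracle limited to 16 locations (got ", n, ")",
         call. = FALSE)
  }
  if (n == 1L) return(list(total = 0, order = character()))
  others <- setdiff(seq_len(n), start)
  m <- length(others)
  d <- dt$d
  full <- bitwShiftL(1L, m) - 1L

  # cost[mask+1, j]: shortest path start -> ... -> others[j] visiting
  # exactly the set `mask` of others.
  cost <- matrix(Inf, full + 1L, m)
  parent <- matrix(NA_integer_, full + 1L, m)
  for (j in seq_len(m)) {
    cost[bitwShiftL(1L, j - 1L) + 1L, j] <- d[start, others[j]]
  }
  for (mask in seq_len(full)) {
    row <- cost[mask + 1L, ]
    live <- which(is.finite(row))
    for (j in live) {
      base <- row[j]
      for (k in seq_len(m)) {
        bit <- bitwShiftL(1L, k - 1L)
        if (bitwAnd(mask, bit) == 0L) {
          nm <- bitwOr(mask, bit) + 1L
          cand <- base + d[others[j], others[k]]
          if (cand < cost[nm, k]) {
            cost[nm, k] <- cand
            parent[nm, k] <- j
          }
        }
      }
    }
  }
  closing <- cost[full + 1L, ] + d[others, start]
  j <- which.min(closing)
  total <- closing[j]
  order_idx <- integer(m)
  mask <- full
  for (pos in rev(seq_len(m))) {
    order_idx[pos] <- j
    pj <- parent[mask + 1L, j]
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
    j <- pj
  }
  list(total = unname(total), order = dt$labels[others[order_idx]])
}
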