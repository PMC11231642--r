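# The small_plan() primitive: randomized nearest-neighbour tour
# construction. At every decision point the remaining destinations are
# sorted by distance from the current location and one is drawn according
# to the configured probability rule; the destination list is rebuilt (and
# the probabilities renormalized) after every visit.

PLAN_MODES <- c("position-weighted", "deterministic-nn", "value-weighted")

#' Planning configuration
#'
#' @param mode Selection rule: `"deterministic-nn"` (always the nearest),
#'   `"position-weighted"` (probability proportional to inverse rank raised
#'   to `weight`), or `"value-weighted"` (normalized reciprocals of each
#'   distance's excess over the minimum).
#' @param weight Positive integer exponent for the position-weighted rule;
#'   defaults to 4 (position-weighted) or 30 (deterministic). Any weight of
#'   10 or more collapses the rule to deterministic nearest-neighbour.
#' @param seed Optional integer seed applied before drawing.
#' @return A `plan_config`.
#' @export
plan_config <- function(mode = c("position-weighted", "deterministic-nn",
                                 "value-weighted"),
                        weight = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(weight)) {
    weight <- if (mode == "deterministic-nn") 30L else 4L
  }
  weight <- as.integer(weight)
  if (is.na(weight) || weight < 1L) {
    stop("weight must be a positive integer", call. = FALSE)
  }
  structure(list(mode = mode, weight = weight, seed = seed),
            class = "plan_config")
}

#' Build a sorted destination list
#'
#' Sorts candidate destinations ascending by distance from the current
#' location; ties are broken by the lower location index so that the
#' deterministic branch is reproducible. `position` is the 1-based rank and
#' `inverse_position` is `m - position + 1` for `m` candidates.
#'
#' @param ids Location identifiers, in location-index order.
#' @param distances Distance from the current location to each id.
#' @return A data frame with columns `id`, `distance`, `position`,
#'   `inverse_position`, sorted by rank.
#' @export
destination_list <- function(ids, distances) {
  m <- length(ids)
  if (m == 0L) stop("empty destination list", call. = FALSE)
  stopifnot(length(distances) == m)
  ord <- order(distances, seq_len(m))
  data.frame(id = as.character(ids)[ord], distance = distances[ord],
             position = seq_len(m), inverse_position = rev(seq_len(m)),
             stringsAsFactors = FALSE)
}

#' Position-weighted selection probabilities
#'
#' For `m` sorted candidates, the probability of the rank-`x` candidate is
#' `inverse_position(x)^weight / sum(inverse_position^weight)`; e.g. with 5
#' candidates at weight 4 the nearest has probability 625/979 (about 64%).
#' The rule depends only on the ranks, never on the distance magnitudes.
#' A weight of 10 or more degenerates to certainty on the nearest
#' candidate.
#'
#' @param dl A [destination_list()].
#' @param weight Positive integer exponent.
#' @return Numeric probability vector aligned with the ranks, summing to 1.
#' @export
position_weighted_probabilities <- function(dl, weight = 4L) {
  m <- nrow(dl)
  if (is.null(m) || m == 0L) stop("empty destination list", call. = FALSE)
  weight <- as.integer(weight)
  if (is.na(weight) || weight < 1L) {
    stop("weight must be a positive integer", call. = FALSE)
  }
  if (weight >= 10L) return(c(1, rep(0, m - 1L)))
  w <- dl$inverse_position^weight
  w / sum(w)
}

#' Value-weighted selection probabilities
#'
#' Each candidate is weighted by the reciprocal of its distance's excess
#' over the minimum distance, with a nominal excess of 1 when the
#' difference is below 1; weights are then normalized. Distances
#' [12, 13, 44] give approximately [49%, 49%, 2%]; equal distances give a
#' uniform vector.
#'
#' @param dl A [destination_list()].
#' @return Numeric probability vector aligned with the ranks, summing to 1.
#' @export
value_weighted_probabilities <- function(dl) {
  m <- nrow(dl)
  if (is.null(m) || m == 0L) stop("empty destination list", call. = FALSE)
  w <- 1 / pmax(dl$distance - dl$distance[1], 1)
  w / sum(w)
}

#' Select a rank from a probability vector
#'
#' Roulette-wheel selection: returns the first rank whose cumulative
#' probability exceeds the uniform draw.
#'
#' @param p Probability vector (non-negative, summing to 1).
#' @param draw A number in `[0, 1)`.
#' @return The selected 1-based rank.
#' @export
select_next <- function(p, draw) {
  if (!is.numeric(draw) || length(draw) != 1L || is.na(draw) ||
      draw < 0 || draw >= 1) {
    stop("draw must be a single number in [0, 1)", call. = FALSE)
  }
  hit <- which(cumsum(p) > draw)
  if (length(hit) == 0L) length(p) else hit[1]
}

# Pure-R reference tour constructor over a distance table. One uniform
# draw is consumed per destination selection in the randomized modes
# (matching the compiled kernel's draw layout); the deterministic mode
# consumes none. Returns ids in visit order plus per-leg distances.
construct_tour <- function(dt, start_id, mode, weight = 4L, draws = NULL) {
  ids <- dt$labels
  remaining <- setdiff(ids, start_id)
  cur <- start_id
  order_out <- character(0)
  legs <- numeric(0)
  step <- 0L
  while (length(remaining) > 0L) {
    dl <- destination_list(remaining, dt$d[cur, remaining])
    if (mode == "deterministic-nn" ||
        (mode == "position-weighted" && weight >= 10L)) {
      rank <- 1L
    } else {
      step <- step + 1L
      draw <- if (is.null(draws)) runif(1) else draws[step]
      p <- switch(mode,
        "position-weighted" = position_weighted_probabilities(dl, weight),
        "value-weighted" = value_weighted_probabilities(dl)
      )
      rank <- select_next(p, draw)
    }
    chosen <- dl$id[rank]
    legs <- c(legs, dl$distance[rank])
    order_out <- c(order_out, chosen)
    remaining <- setdiff(remaining, chosen)
    cur <- chosen
  }
  legs <- c(legs, dt$d[cur, start_id])
  list(order = order_out, legs = legs, total = sum(legs))
}

new_plan_result <- function(module_index, order, legs, start_id,
                            map = NULL) {
  tags <- c(seq_along(order), 0L)
  names(tags) <- c(order, start_id)
  structure(list(module_index = module_index,
                 visit_order = c(order, start_id),
                 leg_distances = legs,
                 total_distance = sum(legs),
                 tag_assignment = tags,
                 map = map),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat("<plan_result", if (!is.na(x$module_index))
    paste0(" [module n=", x$module_index, "]") else "",
    ": total ", x$total_distance, ">\n", sep = "")
  cat("  ", paste(x$visit_order, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Construct a tour over a tagged navigation map
#'
#' The small_plan() primitive for a single module: starting from the
#' `<back>`-tagged cell, repeatedly choose the next `<all>`-tagged
#' destination according to the configured probability rule, re-tag the
#' destinations `<1>, <2>, ...` in visit order, tag the start `<0>`, and
#' return to the start as the final leg.
#'
#' @param map A `nav_map` with at least one `<all>`-tagged cell and a
#'   `<back>`-tagged start cell.
#' @param dt A `distance_table` whose labels cover every tagged cell
#'   (coordinate keys `"x,y,z"`).
#' @param cfg A [plan_config()].
#' @param draws Optional numeric vector of uniform draws in `[0, 1)`, one
#'   per destination decision, overriding the RNG (used to force a
#'   particular route).
#' @return A `plan_result`; its `$map` element is the re-tagged map.
#' @export
small_plan <- function(map, dt, cfg = plan_config(), draws = NULL) {
  stopifnot(inherits(map, "nav_map"), inherits(dt, "distance_table"),
            inherits(cfg, "plan_config"))
  dest_keys <- keys_with_tag(map, "all-marker")
  back <- keys_with_tag(map, "back-marker")
  if (length(dest_keys) == 0L || length(back) != 1L) {
    stop("map needs >= 1 <all>-tagged cell and exactly one <back> start",
         call. = FALSE)
  }
  needed <- c(back, dest_keys)
  missing <- setdiff(needed, dt$labels)
  if (length(missing) > 0L) {
    stop("distance table does not cover: ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  # keep label order = location-index order of the full table
  needed <- needed[order(match(needed, dt$labels))]
  sub <- distance_table(dt$d[needed, needed, drop = FALSE],
                        labels = needed, units = dt$units)
  tour <- construct_tour(sub, back, cfg$mode, cfg$weight, draws)
  for (i in seq_along(tour$order)) {
    map <- add_tag(map, tour$order[i], nav_tag("visit-order", i))
  }
  map <- add_tag(map, back, nav_tag("visit-order", 0L))
  new_plan_result(NA_integer_, tour$order, tour$legs, back, map)
}

#' Emit the move sequence of a plan
#'
#' Locations in ascending visit-order tag, ending with the `<0>`-tagged
#' start: the order in which the move() primitive is repeatedly triggered.
#'
#' @param pr A `plan_result`.
#' @return Data frame with columns `id` and `tag`.
#' @export
move_sequence <- function(pr) {
  stopifnot(inherits(pr, "plan_result"))
  tags <- pr$tag_assignment
  dest <- tags[tags > 0L]
  dest <- dest[order(dest)]
  start <- tags[tags == 0L]
  data.frame(id = c(names(dest), names(start)),
             tag = as.integer(c(dest, start)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plan across the module bank
#'
#' Runs small_plan() in every non-reserved slot: slot n = 1 with the
#' deterministic nearest-neighbour rule, slots n = 2..B-1 with the
#' randomized rule at the given weight. The reserved slot's TempMap tracks
#' the running minimum total; the best module (ties to the lowest n) is
#' selected and its plan returned.
#'
#' @param bank A `module_bank` after [broadcast()].
#' @param dt A `distance_table` covering the tagged cells.
#' @param weight Weight for the randomized modules (default 4).
#' @param mode Randomized rule for slots n >= 2: `"position-weighted"` or
#'   `"value-weighted"`.
#' @return A `bank_result`: `per_module_totals` (named by n = 1..B-1),
#'   `best_index`, `best_plan`, and the updated `bank`.
#' @export
run_bank <- function(bank, dt, weight = 4L,
                     mode = c("position-weighted", "value-weighted")) {
  stopifnot(inherits(bank, "module_bank"), inherits(dt, "distance_table"))
  mode <- match.arg(mode)
  if (!isTRUE(bank$broadcast_done)) {
    stop("bank has not been broadcast", call. = FALSE)
  }
  template <- slot_map(bank, 1L)
  dest_keys <- keys_with_tag(template, "all-marker")
  back <- keys_with_tag(template, "back-marker")
  needed <- c(back, dest_keys)
  ord_idx <- order(match(needed, dt$labels))
  needed <- needed[ord_idx]
  sub <- distance_table(dt$d[needed, needed, drop = FALSE],
                        labels = needed, units = dt$units)
  start_idx <- match(back, needed)

  n_rand <- bank$B - 2L
  det <- tour_totals(sub, start = start_idx, n_modules = 1L,
                     mode = "deterministic-nn")
  totals <- det$totals
  best_order <- det$best_order
  best_n <- 1L
  if (n_rand > 0L) {
    draws <- matrix(runif(n_rand * (n_locations(sub) - 1L)),
                    nrow = n_rand)
    rnd <- tour_totals(sub, start = start_idx, n_modules = n_rand,
                       mode = mode, weight = weight, draws = draws)
    totals <- c(totals, rnd$totals)
    if (rnd$best_total < det$totals[1]) {
      best_order <- rnd$best_order
      best_n <- rnd$best_index + 1L  # kernel row 1 is slot n = 2
    }
  }
  names(totals) <- as.character(seq.int(1L, bank$B - 1L))

  order_ids <- needed[best_order]
  legs <- leg_distances(sub, back, order_ids)
  best_map <- slot_map(bank, best_n)
  for (i in seq_along(order_ids)) {
    best_map <- add_tag(best_map, order_ids[i], nav_tag("visit-order", i))
  }
  best_map <- add_tag(best_map, back, nav_tag("visit-order", 0L))
  bank <- set_slot_map(bank, best_n, best_map)
  bank$slots[[1L]]$temp$minimum <- min(totals)
  bank$slots[[1L]]$temp$best_n <- best_n
  best_plan <- new_plan_result(best_n, order_ids, legs, back, best_map)
  structure(list(per_module_totals = totals, best_index = best_n,
                 best_plan = best_plan, bank = bank),
            class = "bank_result")
}

leg_distances <- function(dt, start_id, order_ids) {
  path <- c(start_id, order_ids, start_id)
  vapply(seq_len(length(path) - 1L),
         function(i) dt$d[path[i], path[i + 1L]], numeric(1))
}

#' @export
print.bank_result <- function(x, ...) {
  cat("<bank_result: best module n = ", x$best_index, ", total ",
      x$best_plan$total_distance, " over ",
      length(x$per_module_totals), " modules>\n", sep = "")
  invisible(x)
}
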