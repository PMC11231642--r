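# R-side wrapper around the compiled tour kernel. The kernel simulates the
# bank's parallel modules sequentially and consumes pre-drawn uniforms, so
# every result is a pure function of (table, mode, weight, draws).

neighbour_order <- function(dt) {
  L <- n_locations(dt)
  t(vapply(seq_len(L), function(i) {
    ord <- order(dt$d[i, ], seq_len(L))  # ties to the lower index
    ord[ord != i]
  }, integer(L - 1L)))
}

#' Tour totals across replicated modules
#'
#' Constructs one randomized nearest-neighbour tour per module over the
#' full distance table and returns the per-module totals plus the best
#' module's visit order (ties to the lowest module row). This is the fast
#' path used by [run_bank()] and the experiment harness; it agrees exactly
#' with the pure-R constructor underlying [small_plan()] on shared draws.
#'
#' @param dt A `distance_table`.
#' @param start 1-based index of the start location.
#' @param n_modules Number of replicated modules.
#' @param mode Selection rule (see [plan_config()]).
#' @param weight Exponent for the position-weighted rule.
#' @param draws Optional `n_modules x (n-1)` matrix of uniforms in
#'   `[0, 1)`; drawn from the R RNG when omitted. Ignored by the
#'   deterministic rule.
#' @return List with `totals`, `best_total`, `best_index`, `best_order`
#'   (1-based location indices, excluding the implicit return to start).
#' @export
tour_totals <- function(dt, start = 1L, n_modules = 1L,
                        mode = c("position-weighted", "deterministic-nn",
                                 "value-weighted"),
                        weight = 4L, draws = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dt, "distance_table"), n_modules >= 1L)
  L <- n_locations(dt)
  if (L < 2L) stop("need at least two locations", call. = FALSE)
  mode_code <- match(mode, c("deterministic-nn", "position-weighted",
                             "value-weighted")) - 1L
  if (is.null(draws)) {
    draws <- if (mode == "deterministic-nn") {
      matrix(0, n_modules, L - 1L)
    } else {
      matrix(runif(n_modules * (L - 1L)), nrow = n_modules)
    }
  }
  stopifnot(nrow(draws) == n_modules, ncol(draws) == L - 1L)
  tour_kernel(dt$d, as.integer(start), neighbour_order(dt),
              mode_code, as.numeric(weight), draws)
}

#' Best-of-bank tour total for one planning episode
#'
#' One full bank episode on a distance table: slot n = 1 runs the
#' deterministic nearest-neighbour rule, slots n = 2..B-1 run the
#' randomized rule, and the minimum total across the non-reserved slots is
#' returned (the reserved slot n = 0 holds no tour). Used by
#' [run_experiment()] where materializing per-slot map copies would add
#' nothing.
#'
#' @param dt A `distance_table`.
#' @param B Bank size (slots n = 0..B-1; n = 0 reserved).
#' @param weight Weight for the randomized slots.
#' @param mode Randomized rule for slots n >= 2.
#' @param start 1-based start location index.
#' @return The best (minimum) tour total across slots n = 1..B-1.
#' @export
bank_best_total <- function(dt, B = 1024L, weight = 4L,
                            mode = c("position-weighted", "value-weighted"),
                            start = 1L) {
  mode <- match.arg(mode)
  stopifnot(B >= 2L)
  det <- tour_totals(dt, start, 1L, "deterministic-nn")$best_total
  if (B == 2L) return(det)
  rnd <- tour_totals(dt, start, B - 2L, mode, weight)$best_total
  min(det, rnd)
}
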