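# Monte Carlo experiment harness: repeated planning episodes on a fixed
# distance table, summarized against the exact oracle, with Welch
# one-tailed t-tests for the between-variant comparisons.

EXPERIMENT_VARIANTS <- c("single-nn", "single-random", "bank-position",
                         "bank-value")

#' Experiment configuration
#'
#' @param variant `"single-nn"` (one module, deterministic),
#'   `"single-random"` (one module, position-weighted randomness),
#'   `"bank-position"` or `"bank-value"` (full bank of B slots, n = 0
#'   reserved, n = 1 deterministic, n >= 2 randomized by the named rule).
#' @param bank_size Bank size B for the bank variants; the conventional
#'   sizes 1024/4096/16384 leave B - 1 usable modules.
#' @param weight Weight for the randomized modules.
#' @param runs Number of independent runs (the replication studies use
#'   100).
#' @param master_seed Integer seed governing all runs.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(variant = c("single-nn", "single-random",
                                          "bank-position", "bank-value"),
                              bank_size = 1024L, weight = 4L,
                              runs = 100L, master_seed = 1L) {
  variant <- match.arg(variant)
  runs <- as.integer(runs)
  stopifnot(runs >= 1L)
  if (variant %in% c("bank-position", "bank-value") && bank_size < 2L) {
    stop("bank variants need bank_size >= 2", call. = FALSE)
  }
  structure(list(variant = variant, bank_size = as.integer(bank_size),
                 weight = as.integer(weight), runs = runs,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

run_best <- function(cfg, dt) {
  switch(cfg$variant,
    "single-nn" = tour_totals(dt, 1L, 1L, "deterministic-nn")$best_total,
    "single-random" = tour_totals(dt, 1L, 1L, "position-weighted",
                                  cfg$weight)$best_total,
    "bank-position" = bank_best_total(dt, cfg$bank_size, cfg$weight,
                                      "position-weighted"),
    "bank-value" = bank_best_total(dt, cfg$bank_size, cfg$weight,
                                   "value-weighted")
  )
}

#' Run a repeated planning experiment
#'
#' Executes `runs` independent planning episodes of the configured variant
#' on the distance table (start = location 1) and summarizes the per-run
#' best totals against the exact oracle. Fully reproducible under a fixed
#' `master_seed`: each run draws a child seed from the master-seeded RNG.
#'
#' @param cfg An [experiment_config()].
#' @param dt A `distance_table`.
#' @return An `experiment_result`: `best_per_run`, `mean`, `sd` (sample
#'   SD; 0 with `sd_defined = FALSE` when `runs == 1`), `optimum`,
#'   `fraction_optimal`, plus the config.
#' @export
run_experiment <- function(cfg, dt) {
  stopifnot(inherits(cfg, "experiment_config"),
            inherits(dt, "distance_table"))
  set.seed(cfg$master_seed)
  run_seeds <- sample.int(.Machine$integer.max, cfg$runs)
  best <- vapply(run_seeds, function(s) {
    set.seed(s)
    run_best(cfg, dt)
  }, numeric(1))
  optimum <- brute_force_shortest(dt, 1L)$total
  sd_defined <- cfg$runs > 1L
  structure(list(
    config = cfg,
    best_per_run = best,
    mean = mean(best),
    sd = if (sd_defined) sd(best) else 0,
    sd_defined = sd_defined,
    optimum = optimum,
    fraction_optimal = mean(best <= optimum + 1e-9)
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result: ", x$config$variant,
      if (grepl("^bank", x$config$variant))
        paste0(" (B = ", x$config$bank_size, ")") else "",
      ", ", x$config$runs, " runs>\n",
      "  mean ", round(x$mean, 1), ", sd ", round(x$sd, 1),
      ", optimum ", x$optimum, ", fraction optimal ",
      x$fraction_optimal, "\n", sep = "")
  invisible(x)
}

#' Sweep the weight parameter
#'
#' One seeded planning episode per weight for the single-module randomized
#' variant and the full-bank variant, mirroring the weight-sensitivity
#' study. Weights above 9 collapse to deterministic nearest-neighbour.
#'
#' @param weights Integer weights in `[1, 30]`.
#' @param dt A `distance_table`.
#' @param bank_size Bank size for the bank variant.
#' @param master_seed Integer seed.
#' @param runs Episodes per weight (best totals are averaged when
#'   `runs > 1`).
#' @return Data frame with columns `weight`, `variant`, `best`.
#' @export
weight_sweep <- function(weights, dt, bank_size = 1024L,
                         master_seed = 1L, runs = 1L) {
  stopifnot(all(weights >= 1L), all(weights <= 30L))
  grid <- expand.grid(weight = as.integer(weights),
                      variant = c("single-random", "bank-position"),
                      stringsAsFactors = FALSE)
  grid$best <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- experiment_config(grid$variant[i], bank_size = bank_size,
                             weight = grid$weight[i], runs = runs,
                             master_seed = master_seed + grid$weight[i])
    mean(run_experiment(cfg, dt)$best_per_run)
  }, numeric(1))
  grid
}

#' Welch one-tailed t-test
#'
#' Tests H1: `mean(a) < mean(b)` with Welch's unequal-variance t statistic
#' and Welch-Satterthwaite degrees of freedom. When exactly one sample has
#' zero variance (e.g. the deterministic nearest-neighbour runs, identical
#' every time), the comparison degenerates to a one-sample t-test against
#' that constant; when both variances are zero the test is undefined and
#' an error is raised.
#'
#' @param a,b Numeric samples, each of size at least 2.
#' @return `list(statistic, df, p.value, method)`; `p.value` is the
#'   one-tailed probability for `mean(a) < mean(b)`.
#' @export
welch_one_tailed <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- var(a)
  vb <- var(b)
  if (va == 0 && vb == 0) {
    stop("both samples have zero variance; test is degenerate",
         call. = FALSE)
  }
  if (vb == 0) {
    tt <- t.test(a, mu = b[1], alternative = "less")
    method <- "one-sample t-test vs zero-variance comparator"
  } else if (va == 0) {
    tt <- t.test(b, mu = a[1], alternative = "greater")
    method <- "one-sample t-test vs zero-variance comparator"
  } else {
    tt <- t.test(a, b, alternative = "less", var.equal = FALSE)
    method <- "Welch two-sample t-test, one-tailed"
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = unname(tt$p.value), method = method)
}
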