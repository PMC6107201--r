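#' Configure one simulated night
#'
#' Bundles every parameter of a single night's run: the arena, the agents,
#' the female decision rule and the movement/contact constants. All agents
#' start synchronously; the night ends when every female has mated or been
#' removed, or after `max_cycles` one-second cycles (a safety cap the runs
#' never approach in practice).
#'
#' @param strategy A [strategy_spec()] or its string form (e.g.
#'   `"best_of_n:3"`); all females in one night use the same rule.
#' @param n_males Number of calling males. Default 25.
#' @param n_females Number of searching females (the study grid uses 5, 10,
#'   15, 20, i.e. operational sex ratios 0.2-0.8).
#' @param distribution Male spatial regime, one of
#'   [spatial_distribution_kinds()].
#' @param pop_mean,pop_sd Mean and sd of the male pulse-number distribution
#'   (pulses/call). Grid means are 6, 12, 18, 24; sd defaults to 2.
#' @param swamp A [swamp_config()].
#' @param speed Female movement per cycle, cm. Default 2.
#' @param contact_radius Distance at which a female reaching her target
#'   mates, cm. Default 5 (about one body length).
#' @param min_spacing Minimum distance between male territories, cm.
#'   Default 50.
#' @param max_cycles Cycle cap. Default 14400 (a four-hour chorus).
#' @param seed Integer seed; one seed fully determines the night.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config("min_threshold:18", n_females = 10, distribution = "random",
#'            pop_mean = 18, seed = 1)
#' @export
sim_config <- function(strategy, n_males = 25, n_females,
                       distribution = c("random", "gaussian", "inverse_gaussian"),
                       pop_mean, pop_sd = 2,
                       swamp = swamp_config(), speed = 2, contact_radius = 5,
                       min_spacing = 50, max_cycles = 14400, seed) {
  if (is.character(strategy)) strategy <- parse_strategy(strategy)
  stopifnot(inherits(strategy, "strategy_spec"),
            n_males >= 1, n_females >= 1, pop_mean > 0, pop_sd > 0,
            speed > 0, contact_radius > 0, max_cycles >= 1,
            is.numeric(seed), length(seed) == 1)
  distribution <- match.arg(distribution, spatial_distribution_kinds())
  if (strategy$kind %in% c("best_of_n", "best_of_n_no_switch") &&
      strategy$param > n_males) {
    stop("best-of-n parameter n (", strategy$param,
         ") exceeds the number of males (", n_males, ")", call. = FALSE)
  }
  structure(list(strategy = strategy, n_males = as.integer(n_males),
                 n_females = as.integer(n_females),
                 distribution = distribution,
                 pop_mean = pop_mean, pop_sd = pop_sd, swamp = swamp,
                 speed = speed, contact_radius = contact_radius,
                 min_spacing = min_spacing,
                 max_cycles = as.integer(max_cycles),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s | %d males (%s, mean PN %g ± %g) | %d females | seed %d\n",
    format(x$strategy), x$n_males, x$distribution, x$pop_mean, x$pop_sd,
    x$n_females, x$seed))
  invisible(x)
}

#' Straight-line approach step
#'
#' Moves a point toward a target along the connecting segment by at most
#' `speed`, never overshooting.
#'
#' @param current,target Numeric `c(x, y)` positions, cm.
#' @param speed Maximum step length, cm per cycle.
#' @return A list with `position` (the new point) and `delta` (the distance
#'   actually covered, `min(speed, remaining distance)`).
#' @examples
#' move_toward(c(0, 0), c(0, 100), 10)  # (0, 10), delta 10
#' move_toward(c(0, 97), c(0, 100), 10) # arrives exactly, delta 3
#' @export
move_toward <- function(current, target, speed) {
  stopifnot(speed > 0)
  v <- target - current
  d <- sqrt(sum(v^2))
  if (d <= speed) return(list(position = target, delta = d))
  list(position = current + v / d * speed, delta = speed)
}

strategy_code <- function(kind) {
  c(random = 0L, best_of_n = 1L, best_of_n_no_switch = 2L,
    min_threshold = 3L)[[kind]]
}

#' Run the cycle loop over explicit agent states
#'
#' The lower-level entry to the simulation: takes already-placed males and
#' females rather than drawing them, and runs the retarget/move/mate cycle
#' loop until every female resolves. Useful for constructed scenarios and
#' for testing the dynamics in isolation; randomness (random-strategy draws,
#' random-walk directions, mating tie-breaks) comes from the current R RNG
#' stream, so wrap in [set.seed()] for reproducibility.
#'
#' @param males A data.frame with columns `id` (1..n, in order), `x`, `y`,
#'   `pulsenumber`.
#' @param females A data.frame with columns `id` (1..n, in order), `x`, `y`.
#' @param strategy A [strategy_spec()] or its string form.
#' @inheritParams sim_config
#' @param keep_log If `TRUE`, attach the retargeting event log.
#' @return A data.frame with one row per female: `female_id`, `mated`,
#'   `mate_id`, `mate_pn`, `distance_cm`, `n_targets`, `cycles`; attributes
#'   `n_cycles`, `timed_out` and optionally `target_log` as in
#'   [run_simulation()].
#' @examples
#' males <- data.frame(id = 1:2, x = c(50, 0), y = c(100, 200),
#'                     pulsenumber = c(8, 16))
#' females <- data.frame(id = 1, x = 0, y = 0)
#' run_night(males, females, "best_of_n:2")  # pursues and mates the PN-16 male
#' @export
run_night <- function(males, females, strategy, swamp = swamp_config(),
                      speed = 2, contact_radius = 5, max_cycles = 14400,
                      keep_log = FALSE) {
  if (is.character(strategy)) strategy <- parse_strategy(strategy)
  check_males(males)
  stopifnot(is.data.frame(females), all(c("x", "y") %in% names(females)),
            inherits(strategy, "strategy_spec"),
            identical(as.integer(males$id), seq_len(nrow(males))),
            speed > 0, contact_radius > 0, max_cycles >= 1)
  res <- run_night_cpp(males$x, males$y, as.integer(males$pulsenumber),
                       females$x, females$y,
                       strategy_code(strategy$kind),
                       as.numeric(strategy$param),
                       speed, contact_radius, as.integer(max_cycles),
                       swamp$width, swamp$length, keep_log)
  out <- data.frame(female_id = seq_len(nrow(females)),
                    mated = res$mated, mate_id = res$mate_id,
                    mate_pn = res$mate_pn, distance_cm = res$distance,
                    n_targets = res$n_targets, cycles = res$cycles_active)
  attr(out, "n_cycles") <- res$n_cycles
  attr(out, "timed_out") <- res$timed_out
  if (keep_log) {
    log <- res$log
    log$pulsenumber <- males$pulsenumber[log$male_id]
    log$reason <- c("initial", "target_mated", "better_male")[log$reason + 1L]
    attr(out, "target_log") <-
      log[, c("female_id", "male_id", "pulsenumber", "reason", "cycle")]
  }
  out
}

#' Run one night of the chorus
#'
#' Seeds the RNG, places the agents ([sample_male_positions()],
#' [sample_pulsenumbers()], [sample_female_positions()]) and runs the
#' 1-second cycle loop: every searching female re-evaluates her target
#' according to her rule, all females then step toward their targets, and
#' males with a pursuing female within the contact radius mate (the nearest
#' such female wins; both leave the pool). Minimum-threshold females for whom
#' no acceptable male exists take a single random-walk step and are removed
#' unmated. Identical configs (including seed) give identical outcomes.
#'
#' @param config A [sim_config()].
#' @param keep_log If `TRUE`, attach the per-female retargeting event log.
#' @return A data.frame with one row per female: `female_id`, `mated`,
#'   `mate_id` and `mate_pn` (`NA` unless mated), `distance_cm`, `n_targets`
#'   (distinct consecutive targets; A-B-A counts 3), `cycles`, plus the condition
#'   labels `strategy`, `strategy_class`, `param`, `n_males`, `n_females`,
#'   `distribution`, `pop_mean`, `seed`. Attributes: `n_cycles` (length of
#'   the night), `timed_out`, and (with `keep_log`) `target_log`, a
#'   data.frame of events `female_id`, `male_id`, `pulsenumber`, `reason`
#'   (`"initial"`, `"target_mated"`, `"better_male"`) and `cycle`.
#' @examples
#' out <- run_simulation(sim_config("best_of_n:3", n_females = 10,
#'                                  distribution = "random", pop_mean = 12,
#'                                  seed = 42))
#' mean(out$distance_cm)
#' @export
run_simulation <- function(config, keep_log = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  males <- sample_male_positions(config$distribution, config$n_males,
                                 config$min_spacing, config$swamp)
  males$pulsenumber <- sample_pulsenumbers(config$pop_mean, config$pop_sd,
                                           config$n_males)
  females <- sample_female_positions(config$n_females, config$swamp)

  night <- run_night(males, females, config$strategy, swamp = config$swamp,
                     speed = config$speed,
                     contact_radius = config$contact_radius,
                     max_cycles = config$max_cycles, keep_log = keep_log)

  out <- cbind(
    data.frame(strategy = format(config$strategy),
               strategy_class = config$strategy$kind,
               param = as.numeric(config$strategy$param),
               n_males = config$n_males,
               n_females = config$n_females,
               distribution = config$distribution,
               pop_mean = config$pop_mean,
               seed = config$seed),
    night)
  attr(out, "n_cycles") <- attr(night, "n_cycles")
  attr(out, "timed_out") <- attr(night, "timed_out")
  if (keep_log) attr(out, "target_log") <- attr(night, "target_log")
  out
}
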