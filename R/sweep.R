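#' Define a factorial sweep
#'
#' The study design crosses the strategy:parameter pairs with the male
#' population quality means, the number of females (sex ratio), and the male
#' spatial distribution, and runs every cell with `replicates` independent
#' seeds. The defaults reproduce the full design: 10 strategy pairs
#' (best-of-1..5, thresholds 6/12/18/24, random) x 4 quality means x
#' 4 female counts x 3 distributions x 100 replicates = 48,000 nights.
#'
#' @param strategies Character vector of strategy labels (see
#'   [parse_strategy()]).
#' @param pop_means Male population mean pulse numbers.
#' @param n_females_list Numbers of females per night.
#' @param distributions Male spatial regimes.
#' @param replicates Independent nights per cell.
#' @param base_seed Integer; per-cell seeds are derived from it so any cell
#'   can be re-run in isolation.
#' @param ... Further arguments passed to [sim_config()] (e.g. `speed`,
#'   `n_males`, `swamp`).
#' @return An object of class `sweep_config`.
#' @examples
#' sweep_config(replicates = 2)
#' @export
sweep_config <- function(strategies = default_strategies(),
                         pop_means = c(6, 12, 18, 24),
                         n_females_list = c(5, 10, 15, 20),
                         distributions = spatial_distribution_kinds(),
                         replicates = 100, base_seed = 1, ...) {
  stopifnot(length(strategies) > 0, length(pop_means) > 0,
            length(n_females_list) > 0, length(distributions) > 0,
            replicates >= 1)
  lapply(strategies, parse_strategy)  # validate early
  structure(list(strategies = strategies, pop_means = pop_means,
                 n_females_list = n_females_list,
                 distributions = distributions,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 sim_args = list(...)),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  n <- length(x$strategies) * length(x$pop_means) *
    length(x$n_females_list) * length(x$distributions) * x$replicates
  cat(sprintf(
    "<sweep_config> %d strategies x %d means x %d female counts x %d distributions x %d reps = %d runs\n",
    length(x$strategies), length(x$pop_means), length(x$n_females_list),
    length(x$distributions), x$replicates, n))
  invisible(x)
}

#' @rdname sweep_config
#' @export
default_strategies <- function() {
  c(paste0("best_of_n:", 1:5), paste0("min_threshold:", c(6, 12, 18, 24)),
    "random")
}

# Stable 31-bit polynomial hash of a label string. Exact in double
# arithmetic (intermediate values stay < 2^53), so identical across
# platforms and R versions.
hash31 <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Per-cell reproducible seed
#'
#' Derives the seed of one sweep cell/replicate from the base seed and the
#' cell labels via a stable string hash, so a single cell can be re-run in
#' isolation (and in any execution order) with identical results.
#'
#' @param base_seed Integer base seed of the sweep.
#' @param strategy,pop_mean,n_females,distribution Cell labels.
#' @param replicate Replicate index within the cell.
#' @return A positive integer seed below 2^31.
#' @export
cell_seed <- function(base_seed, strategy, pop_mean, n_females,
                      distribution, replicate) {
  key <- paste(strategy, pop_mean, n_females, distribution, replicate,
               sep = "|")
  s <- bitwXor(as.integer(base_seed), hash31(key)) %% 2147483647L
  if (s <= 0L) s + 1L else s
}

#' Expand a sweep into individual run configurations
#'
#' @param sweep A [sweep_config()].
#' @return A data.frame with one row per run (`strategy`, `pop_mean`,
#'   `n_females`, `distribution`, `replicate`, `seed`) in a deterministic
#'   enumeration order; with the defaults, 48,000 rows.
#' @examples
#' nrow(expand_sweep(sweep_config(replicates = 1)))  # 480
#' @export
expand_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_config"))
  grid <- expand.grid(replicate = seq_len(sweep$replicates),
                      distribution = sweep$distributions,
                      n_females = sweep$n_females_list,
                      pop_mean = sweep$pop_means,
                      strategy = sweep$strategies,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("strategy", "pop_mean", "n_females", "distribution",
                   "replicate")]
  grid$seed <- mapply(cell_seed, strategy = grid$strategy,
                      pop_mean = grid$pop_mean, n_females = grid$n_females,
                      distribution = grid$distribution,
                      replicate = grid$replicate,
                      MoreArgs = list(base_seed = sweep$base_seed),
                      USE.NAMES = FALSE)
  rownames(grid) <- NULL
  grid
}

#' Run a sweep of simulated nights
#'
#' Runs every row of the expanded design through [run_simulation()] and
#' concatenates the per-female outcome rows. Because each run carries its own
#' derived seed, the pooled table is invariant to execution order and any
#' subset of rows can be recomputed bit-for-bit.
#'
#' @param sweep A [sweep_config()], or a data.frame as returned by
#'   [expand_sweep()] (possibly subset) to run selected cells.
#' @param progress_every Print a progress line every this many runs;
#'   `0` (default) is silent.
#' @param ... Arguments passed on to [sim_config()] (ignored when `sweep` is
#'   a `sweep_config`, which carries its own `sim_args`).
#' @return A data.frame of per-female outcomes (see [run_simulation()]),
#'   `sum(n_females)` rows.
#' @examples
#' sw <- sweep_config(strategies = c("best_of_n:1", "random"),
#'                    pop_means = 12, n_females_list = 5,
#'                    distributions = "random", replicates = 2)
#' out <- run_sweep(sw)
#' table(out$strategy)
#' @export
run_sweep <- function(sweep, progress_every = 0, ...) {
  if (inherits(sweep, "sweep_config")) {
    sim_args <- sweep$sim_args
    grid <- expand_sweep(sweep)
  } else {
    sim_args <- list(...)
    grid <- sweep
    stopifnot(is.data.frame(grid),
              all(c("strategy", "pop_mean", "n_females", "distribution",
                    "seed") %in% names(grid)))
  }
  n <- nrow(grid)
  pieces <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- do.call(sim_config, c(list(
      strategy = grid$strategy[i], n_females = grid$n_females[i],
      distribution = grid$distribution[i], pop_mean = grid$pop_mean[i],
      seed = grid$seed[i]), sim_args))
    pieces[[i]] <- tryCatch(run_simulation(cfg), error = function(e) {
      stop("sweep cell failed (", grid$strategy[i], ", pop_mean ",
           grid$pop_mean[i], ", ", grid$n_females[i], " females, ",
           grid$distribution[i], ", seed ", grid$seed[i], "): ",
           conditionMessage(e), call. = FALSE)
    })
    if (progress_every > 0 && i %% progress_every == 0) {
      message("run ", i, "/", n)
    }
  }
  out <- data.table::rbindlist(pieces)
  data.table::setDF(out)
  out
}

#' Write / read an outcome table
#'
#' Outcome tables are plain delimited text with a header, one row per
#' female.
#'
#' @param outcomes A data.frame of per-female outcomes.
#' @param path File path.
#' @return `write_outcomes` returns `path` invisibly; `read_outcomes` the
#'   data.frame.
#' @export
write_outcomes <- function(outcomes, path) {
  data.table::fwrite(outcomes, path)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  out <- data.table::fread(path, data.table = FALSE)
  out
}
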