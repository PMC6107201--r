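#' Female decision rules
#'
#' A strategy specification pairs a rule kind with its parameter:
#' * `best_of_n` — assess the `n` spatially closest males, target the one
#'   with the highest pulse number; the set is re-evaluated every cycle.
#' * `best_of_n_no_switch` — same choice rule, but the target is reconsidered
#'   only after the current target mates with another female.
#' * `min_threshold` — target the closest male whose pulse number is at least
#'   the acceptance threshold `theta`; the target is kept until it mates.
#' * `random` — target a male drawn uniformly from the whole chorus; kept
#'   until it mates.
#'
#' @param kind One of `"best_of_n"`, `"best_of_n_no_switch"`,
#'   `"min_threshold"`, `"random"`.
#' @param param `n` (a positive count) for the best-of-n kinds, the threshold
#'   `theta` in pulses/call for `min_threshold`; ignored for `random`.
#' @return An object of class `strategy_spec` with elements `kind`, `param`
#'   and `class` (the strategy class label used in pooled summaries:
#'   best-of-n kinds keep their own class).
#' @examples
#' strategy_spec("best_of_n", 3)
#' strategy_spec("min_threshold", 18)
#' parse_strategy("best_of_n:3")
#' @export
strategy_spec <- function(kind = c("best_of_n", "best_of_n_no_switch",
                                   "min_threshold", "random"),
                          param = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("best_of_n", "best_of_n_no_switch")) {
    stopifnot("best-of-n needs a positive integer n" =
                is.numeric(param) && length(param) == 1 &&
                param >= 1 && param == round(param))
    param <- as.integer(param)
  } else if (kind == "min_threshold") {
    stopifnot("min_threshold needs a numeric threshold" =
                is.numeric(param) && length(param) == 1 && param > 0)
    param <- as.numeric(param)
  } else {
    param <- NA_real_
  }
  structure(list(kind = kind, param = param), class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat("<strategy_spec>", format(x), "\n")
  invisible(x)
}

#' @export
format.strategy_spec <- function(x, ...) {
  if (x$kind == "random") "random" else paste0(x$kind, ":", x$param)
}

#' @rdname strategy_spec
#' @param label A configuration string such as `"best_of_n:3"`,
#'   `"best_of_n_no_switch:3"`, `"min_threshold:18"` or `"random"`.
#' @export
parse_strategy <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(strategy_spec(parts))
  strategy_spec(parts[1], as.numeric(parts[2]))
}

# males: data.frame with id, x, y, pulsenumber (alive males only)
check_males <- function(males) {
  stopifnot(is.data.frame(males),
            all(c("id", "x", "y", "pulsenumber") %in% names(males)))
}

#' The k closest males to a position
#'
#' Sorts alive males by ascending Euclidean distance from `position`
#' (deterministic tie-break by lower id) and returns the first `k` ids.
#'
#' @param position Numeric `c(x, y)` in cm.
#' @param males A data.frame of alive males with columns `id`, `x`, `y`,
#'   `pulsenumber`.
#' @param k Number of males wanted; saturates at the number of alive males.
#' @return Integer vector of up to `k` male ids, nearest first; length 0 when
#'   no males are alive.
#' @export
closest_males <- function(position, males, k) {
  check_males(males)
  stopifnot(k >= 1)
  if (nrow(males) == 0) return(integer(0))
  d2 <- (males$x - position[1])^2 + (males$y - position[2])^2
  ord <- order(d2, males$id)
  males$id[ord][seq_len(min(k, nrow(males)))]
}

#' Best-of-n target choice
#'
#' Among the `n` closest alive males, the male with the highest pulse number;
#' ties on pulse number go to the closer male, then to the lower id.
#'
#' @inheritParams closest_males
#' @param n Size of the assessment set.
#' @return A male id, or `NA_integer_` when no males are alive.
#' @examples
#' males <- data.frame(id = 1:3, x = c(10, 20, 30), y = 0,
#'                     pulsenumber = c(5, 9, 7))
#' choose_target_best_of_n(c(0, 0), males, 3)  # the pulse-9 male
#' choose_target_best_of_n(c(0, 0), males, 1)  # the closest, regardless
#' @export
choose_target_best_of_n <- function(position, males, n) {
  check_males(males)
  if (nrow(males) == 0) return(NA_integer_)
  ids <- closest_males(position, males, n)
  sub <- males[match(ids, males$id), ]
  d2 <- (sub$x - position[1])^2 + (sub$y - position[2])^2
  ord <- order(-sub$pulsenumber, d2, sub$id)
  sub$id[ord[1]]
}

#' Minimum-threshold target choice
#'
#' The closest alive male whose pulse number is at least `theta`. Because
#' females hear the whole chorus, a `NA` return means no acceptable male
#' exists now or ever (males are only removed), so the caller removes the
#' female after a one-cycle random walk.
#'
#' @inheritParams closest_males
#' @param theta Acceptance threshold, pulses per call.
#' @return A male id, or `NA_integer_` when no alive male meets the threshold.
#' @export
choose_target_min_threshold <- function(position, males, theta) {
  check_males(males)
  ok <- males$pulsenumber >= theta
  if (!any(ok)) return(NA_integer_)
  closest_males(position, males[ok, , drop = FALSE], 1)
}

#' Random target choice
#'
#' A male drawn uniformly from all alive males, anywhere in the swamp.
#'
#' @inheritParams closest_males
#' @return A male id, or `NA_integer_` when no males are alive.
#' @export
choose_target_random <- function(males) {
  check_males(males)
  if (nrow(males) == 0) return(NA_integer_)
  males$id[floor(stats::runif(1) * nrow(males)) + 1]
}
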