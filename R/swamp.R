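#' Define the swamp arena
#'
#' The chorus takes place in a fixed rectangular "swamp" with hard walls
#' (no wrap-around). The default is a realistic 10 x 25 m wetland, in cm.
#'
#' @param width Arena width (x extent) in cm. Default 1000.
#' @param length Arena length (y extent) in cm. Default 2500.
#' @return An object of class `swamp_config` with elements `width` and
#'   `length`.
#' @examples
#' swamp_config()
#' swamp_config(width = 500, length = 500)
#' @export
swamp_config <- function(width = 1000, length = 2500) {
  stopifnot(is.numeric(width), length(width) == 1, width > 0,
            is.numeric(length), base::length(length) == 1, length > 0)
  structure(list(width = as.numeric(width), length = as.numeric(length)),
            class = "swamp_config")
}

#' @export
print.swamp_config <- function(x, ...) {
  cat(sprintf("<swamp_config> %g x %g cm (hard walls)\n", x$width, x$length))
  invisible(x)
}

#' Spatial placement regimes for males
#'
#' @return Character vector of the supported male spatial distributions:
#'   `"gaussian"` (clustered at the swamp centre), `"inverse_gaussian"`
#'   (more males toward the edges, as on pond shorelines) and `"random"`
#'   (uniform).
#' @export
spatial_distribution_kinds <- function() {
  c("gaussian", "inverse_gaussian", "random")
}

# Draw one coordinate in [0, extent] under the requested regime.
# gaussian: truncated normal centred at extent/2 with sd = extent/6
# (~99.7% of mass inside before truncation); inverse_gaussian: the same
# draw reflected by a half-extent shift so density peaks at both edges.
sample_axis <- function(kind, extent) {
  if (kind == "random") return(stats::runif(1, 0, extent))
  repeat {
    u <- stats::rnorm(1, mean = extent / 2, sd = extent / 6)
    if (u >= 0 && u <= extent) break
  }
  if (kind == "inverse_gaussian") u <- (u + extent / 2) %% extent
  u
}

#' Place males in the swamp
#'
#' Males are placed sequentially; each occupies a territory of at least
#' `min_spacing` diameter, so a candidate closer than `min_spacing` to any
#' already-placed male is rejected and redrawn. Positions are fixed for the
#' night (males do not move).
#'
#' @param kind One of [spatial_distribution_kinds()].
#' @param n_males Number of males (>= 1).
#' @param min_spacing Minimum pairwise distance between males, cm.
#'   Default 50 (territory diameter).
#' @param swamp A [swamp_config()].
#' @param max_rejections Retry budget per male before the placement is
#'   declared infeasible. Default 10000.
#' @return A data.frame with columns `id`, `x`, `y` (cm).
#' @examples
#' set.seed(1)
#' sample_male_positions("random", 25, 50, swamp_config())
#' @export
sample_male_positions <- function(kind = c("random", "gaussian", "inverse_gaussian"),
                                  n_males, min_spacing = 50,
                                  swamp = swamp_config(),
                                  max_rejections = 10000) {
  kind <- match.arg(kind, choices = spatial_distribution_kinds())
  stopifnot(n_males >= 1, min_spacing >= 0, inherits(swamp, "swamp_config"))
  xs <- numeric(n_males)
  ys <- numeric(n_males)
  sp2 <- min_spacing^2
  for (i in seq_len(n_males)) {
    rejections <- 0L
    repeat {
      x <- sample_axis(kind, swamp$width)
      y <- sample_axis(kind, swamp$length)
      ok <- i == 1L ||
        all((xs[seq_len(i - 1L)] - x)^2 + (ys[seq_len(i - 1L)] - y)^2 >= sp2)
      if (ok) break
      rejections <- rejections + 1L
      if (rejections >= max_rejections) {
        stop("placement infeasible: could not place male ", i, " of ", n_males,
             " with min_spacing ", min_spacing, " cm after ", max_rejections,
             " rejections", call. = FALSE)
      }
    }
    xs[i] <- x
    ys[i] <- y
  }
  data.frame(id = seq_len(n_males), x = xs, y = ys)
}

#' Draw male call pulse numbers
#'
#' Each male's advertisement-call quality is its *pulse number* (pulses per
#' call), drawn once per night from a normal distribution, rounded to the
#' nearest integer and clamped to at least 1 (pulse counts are integers and
#' cannot be non-positive). The pulse number of a given male never changes.
#'
#' @param pop_mean Population mean pulses per call (the study grid uses
#'   6, 12, 18 or 24).
#' @param pop_sd Population standard deviation, pulses per call. Default 2.
#' @param n_males Number of draws.
#' @return Integer vector of length `n_males`, all values >= 1.
#' @examples
#' set.seed(1)
#' sample_pulsenumbers(24, 2, 25)
#' @export
sample_pulsenumbers <- function(pop_mean, pop_sd = 2, n_males) {
  stopifnot(pop_mean > 0, pop_sd > 0, n_males >= 1)
  pmax(1L, as.integer(round(stats::rnorm(n_males, pop_mean, pop_sd))))
}

#' Place females on the swamp edge
#'
#' Females enter the chorus from the swamp margins: each is placed uniformly
#' along the full perimeter (all four edges, in proportion to their length).
#'
#' @param n_females Number of females (>= 1).
#' @param swamp A [swamp_config()].
#' @return A data.frame with columns `id`, `x`, `y`; every point lies exactly
#'   on the swamp boundary.
#' @examples
#' set.seed(1)
#' sample_female_positions(20, swamp_config())
#' @export
sample_female_positions <- function(n_females, swamp = swamp_config()) {
  stopifnot(n_females >= 1, inherits(swamp, "swamp_config"))
  w <- swamp$width
  l <- swamp$length
  per <- 2 * (w + l)
  s <- stats::runif(n_females, 0, per)
  x <- numeric(n_females)
  y <- numeric(n_females)
  # walk the perimeter: bottom, right, top, left
  b1 <- s < w
  b2 <- !b1 & s < w + l
  b3 <- !b1 & !b2 & s < 2 * w + l
  b4 <- !(b1 | b2 | b3)
  x[b1] <- s[b1];               y[b1] <- 0
  x[b2] <- w;                   y[b2] <- s[b2] - w
  x[b3] <- 2 * w + l - s[b3];   y[b3] <- l
  x[b4] <- 0;                   y[b4] <- per - s[b4]
  data.frame(id = seq_len(n_females), x = x, y = y)
}
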