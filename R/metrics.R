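ci_half <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  1.96 * stats::sd(x, na.rm = TRUE) / sqrt(n)
}

#' Grouped summaries of the dependent variables
#'
#' Reports, per group, the mean pulse number of male mates, the mean
#' distance traveled, the mean number of distinct males targeted, and the
#' percentage of females that mated, each with a 95% confidence half-width
#' (1.96 standard errors). By convention mate pulse number is averaged over
#' mated females only; distance can be restricted the same way to compare
#' with mated-only travel costs.
#'
#' The unit of analysis defaults to the simulation: each night's females are
#' averaged first and nights are weighted equally, because females competing
#' in the same chorus are not independent observations (pooling their rows
#' directly would both pseudoreplicate and over-weight the crowded nights).
#' `unit = "female"` pools the raw female rows instead.
#'
#' @param outcomes An outcome table from [run_simulation()] or
#'   [run_sweep()].
#' @param group_by Character vector of grouping columns (default
#'   `"strategy_class"`; use `"strategy"` for per strategy:parameter rows).
#' @param mated_only_pn Average mate pulse number over mated females only
#'   (default `TRUE`; unmated females have no mate).
#' @param mated_only_dist Restrict the distance average to mated females
#'   (default `FALSE`: non-maters, whose travel is one random-walk step, are
#'   pooled in).
#' @param unit `"simulation"` (default) or `"female"`; see Details.
#' @return A data.frame with the grouping columns plus `n` (units),
#'   `percent_mated`, `mean_pn`, `ci_pn`, `mean_dist`, `ci_dist`,
#'   `mean_targets`, `ci_targets`.
#' @examples
#' out <- run_sweep(sweep_config(strategies = c("best_of_n:2", "random"),
#'                               pop_means = 12, n_females_list = 10,
#'                               distributions = "random", replicates = 3))
#' summarize_outcomes(out)
#' @export
summarize_outcomes <- function(outcomes, group_by = "strategy_class",
                               mated_only_pn = TRUE,
                               mated_only_dist = FALSE,
                               unit = c("simulation", "female")) {
  stopifnot(is.data.frame(outcomes), nrow(outcomes) > 0,
            all(group_by %in% names(outcomes)))
  unit <- match.arg(unit)
  dt <- data.table::as.data.table(outcomes)
  mated <- NULL  # NSE note for R CMD check
  agg <- function(d, by) d[, {
    pn <- if (mated_only_pn) mate_pn[mated] else ifelse(mated, mate_pn, 0)
    dist <- if (mated_only_dist) distance_cm[mated] else distance_cm
    list(percent_mated = 100 * mean(mated),
         mean_pn = if (length(pn)) mean(pn) else NA_real_,
         mean_dist = if (length(dist)) mean(dist) else NA_real_,
         mean_targets = mean(n_targets))
  }, by = by]
  if (unit == "simulation") {
    run_cols <- unique(c(group_by,
                         intersect(c("strategy", "pop_mean", "n_females",
                                     "distribution", "seed"), names(dt))))
    dt <- agg(dt, run_cols)
    summ <- dt[, list(
      n = .N,
      percent_mated = mean(percent_mated),
      mean_pn = mean(mean_pn, na.rm = TRUE),
      ci_pn = ci_half(mean_pn),
      mean_dist = mean(mean_dist, na.rm = TRUE),
      ci_dist = ci_half(mean_dist),
      mean_targets = mean(mean_targets),
      ci_targets = ci_half(mean_targets)), by = group_by]
  } else {
    summ <- dt[, {
      pn <- if (mated_only_pn) mate_pn[mated] else ifelse(mated, mate_pn, 0)
      dist <- if (mated_only_dist) distance_cm[mated] else distance_cm
      list(n = .N,
           percent_mated = 100 * mean(mated),
           mean_pn = mean(pn), ci_pn = ci_half(pn),
           mean_dist = mean(dist), ci_dist = ci_half(dist),
           mean_targets = mean(n_targets), ci_targets = ci_half(n_targets))
    }, by = group_by]
  }
  data.table::setorderv(summ, group_by)
  data.table::setDF(summ)
  summ
}

#' Fitness weighting parameters
#'
#' The nightly fitness of a strategy trades the quality of mates obtained
#' against the distance traveled to get them, both normalised by the extremes
#' observed over the entire outcome database:
#'
#' `fitness = (1 - alpha) * (MeanPN - MinPN) / (MaxPN - MinPN) +
#'   alpha * (1 - (MeanDist - MinDist) / (MaxDist - MinDist))`
#'
#' `alpha` in \[0, 1\] sets the environmental pressure: near 0, mate quality
#' dominates (e.g. ample energy reserves); near 1, travel cost dominates
#' (e.g. predation pressure). For the fitness inputs, females that did not
#' mate contribute a mate quality of 0 (the lost-opportunity cost), while
#' the PN extremes are taken over mated males and the distance extremes over
#' all females in the database.
#'
#' @param outcomes Outcome table over which to take the global extremes.
#' @param alpha Weight in \[0, 1\].
#' @return An object of class `fitness_params` with elements `alpha`,
#'   `min_pn`, `max_pn`, `min_dist`, `max_dist`.
#' @examples
#' fitness_params(run_simulation(sim_config("random", n_females = 10,
#'   distribution = "random", pop_mean = 12, seed = 1)), alpha = 0.5)
#' @export
fitness_params <- function(outcomes, alpha = 0.5) {
  stopifnot(is.data.frame(outcomes), any(outcomes$mated),
            alpha >= 0, alpha <= 1)
  pn <- outcomes$mate_pn[outcomes$mated]
  p <- structure(list(alpha = alpha,
                      min_pn = min(pn), max_pn = max(pn),
                      min_dist = min(outcomes$distance_cm),
                      max_dist = max(outcomes$distance_cm)),
                 class = "fitness_params")
  validate_fitness_params(p)
  p
}

validate_fitness_params <- function(p) {
  stopifnot(p$alpha >= 0, p$alpha <= 1)
  if (p$max_pn <= p$min_pn || p$max_dist <= p$min_dist) {
    stop("degenerate fitness extremes: max must exceed min for both pulse ",
         "number and distance", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.fitness_params <- function(x, ...) {
  cat(sprintf("<fitness_params> alpha %g | PN [%g, %g] | dist [%g, %g] cm\n",
              x$alpha, x$min_pn, x$max_pn, x$min_dist, x$max_dist))
  invisible(x)
}

#' @rdname fitness_params
#' @param params A `fitness_params` object.
#' @param mean_pn Mean mate pulse number of a group (non-maters counted
#'   as 0).
#' @param mean_dist Mean distance traveled by the group's females, cm.
#' @return `fitness()` returns the unitless fitness value; with valid
#'   extremes and means inside them, in \[0, 1\].
#' @examples
#' p <- structure(list(alpha = 0.5, min_pn = 6, max_pn = 24,
#'                     min_dist = 100, max_dist = 1100),
#'                class = "fitness_params")
#' fitness(p, mean_pn = 15, mean_dist = 600)  # 0.5
#' @export
fitness <- function(params, mean_pn, mean_dist) {
  validate_fitness_params(params)
  q <- (mean_pn - params$min_pn) / (params$max_pn - params$min_pn)
  d <- (mean_dist - params$min_dist) / (params$max_dist - params$min_dist)
  (1 - params$alpha) * q + params$alpha * (1 - d)
}

#' Fitness of each strategy class across a grid of alpha weights
#'
#' @param outcomes Outcome table (the extremes are taken over all of it).
#' @param alphas Numeric vector of weights in \[0, 1\].
#' @param group_by Grouping column, default `"strategy_class"`.
#' @return A data.frame with columns `group`, `alpha`, `mean_pn`,
#'   `mean_dist`, `fitness`.
#' @export
fitness_by_class <- function(outcomes, alphas = seq(0, 1, by = 0.05),
                             group_by = "strategy_class") {
  stopifnot(all(alphas >= 0 & alphas <= 1))
  cls <- summarize_outcomes(outcomes, group_by = group_by,
                            mated_only_pn = FALSE)  # non-maters count as 0
  base <- fitness_params(outcomes, alpha = 0)
  res <- do.call(rbind, lapply(alphas, function(a) {
    p <- base
    p$alpha <- a
    data.frame(group = cls[[group_by]], alpha = a,
               mean_pn = cls$mean_pn, mean_dist = cls$mean_dist,
               fitness = fitness(p, cls$mean_pn, cls$mean_dist))
  }))
  rownames(res) <- NULL
  res
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled standard deviation weighted by each group's `n - 1`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return The effect size (positive when `a` has the larger mean).
#' @examples
#' cohens_d(rnorm(100, 1), rnorm(100, 0))
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation: Cohen's d undefined",
                    call. = FALSE)
  (mean(a) - mean(b)) / sp
}

#' Univariate ANOVA report for one dependent variable
#'
#' A thin reporting layer over [stats::aov()]: fits the full-factorial
#' analysis of one dependent variable against the four design factors
#' (strategy:parameter pair, number of females, male spatial distribution,
#' male population pulse number) and returns the term table. Factors with a
#' single level in the data are dropped with a warning. `mate_pn` is
#' analysed over mated females only.
#'
#' @param outcomes Outcome table from [run_sweep()].
#' @param response One of `"mate_pn"`, `"distance_cm"`, `"n_targets"`.
#' @return A data.frame with columns `term`, `df`, `sum_sq`, `f_value`,
#'   `p_value` (the residual row carries `NA` statistics), and the fitted
#'   model as attribute `fit` (for [stats::TukeyHSD()] follow-ups).
#' @export
anova_report <- function(outcomes,
                         response = c("distance_cm", "mate_pn", "n_targets")) {
  response <- match.arg(response)
  dat <- outcomes
  if (response == "mate_pn") dat <- dat[dat$mated, , drop = FALSE]
  stopifnot(nrow(dat) > 0)
  dat <- data.frame(y = dat[[response]],
                    sp = factor(dat$strategy),
                    nf = factor(dat$n_females),
                    md = factor(dat$distribution),
                    mp = factor(dat$pop_mean))
  keep <- vapply(dat[c("sp", "nf", "md", "mp")],
                 function(f) nlevels(droplevels(f)) > 1, logical(1))
  if (!all(keep)) {
    warning("dropping single-level factor(s): ",
            paste(names(keep)[!keep], collapse = ", "))
  }
  terms <- names(keep)[keep]
  if (length(terms) == 0) stop("no factor varies in these outcomes",
                               call. = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " * ")))
  fit <- stats::aov(fml, data = droplevels(dat))
  tab <- summary(fit)[[1]]
  out <- data.frame(term = trimws(rownames(tab)),
                    df = tab$Df, sum_sq = tab$`Sum Sq`,
                    f_value = tab$`F value`, p_value = tab$`Pr(>F)`)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
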