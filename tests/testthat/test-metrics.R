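# small hand-checkable outcome fixture: 2 strategies x 2 nights x 5 females
fixture_outcomes <- function() {
  grid <- expand.grid(female_id = 1:5, seed = c(100, 200),
                      strategy = c("s_a", "s_b"))
  out <- data.frame(strategy = grid$strategy,
                    strategy_class = grid$strategy, param = 1,
                    n_males = 25, n_females = 5, distribution = "random",
                    pop_mean = 12, seed = grid$seed,
                    female_id = grid$female_id)
  set.seed(99)
  out$mated <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 4)
  out$mate_pn <- ifelse(out$mated, sample(6:24, 20, replace = TRUE), NA)
  out$mate_id <- ifelse(out$mated, out$female_id, NA)
  out$distance_cm <- round(runif(20, 2, 900), 1)
  out$n_targets <- sample(0:4, 20, replace = TRUE)
  out$cycles <- sample(10:500, 20)
  out
}

test_that("summaries equal a brute-force recomputation for both units", {
  out <- fixture_outcomes()
  # female unit: straight pooled means
  s <- summarize_outcomes(out, "strategy_class", unit = "female")
  for (g in c("s_a", "s_b")) {
    rows <- out[out$strategy_class == g, ]
    i <- s$strategy_class == g
    expect_equal(s$mean_pn[i], mean(rows$mate_pn[rows$mated]))
    expect_equal(s$mean_dist[i], mean(rows$distance_cm))
    expect_equal(s$percent_mated[i], 100 * mean(rows$mated))
    expect_equal(s$mean_targets[i], mean(rows$n_targets))
    expect_equal(s$ci_dist[i],
                 1.96 * sd(rows$distance_cm) / sqrt(nrow(rows)))
  }
  # simulation unit: nights averaged first, then weighted equally
  s2 <- summarize_outcomes(out, "strategy_class", unit = "simulation")
  for (g in c("s_a", "s_b")) {
    rows <- out[out$strategy_class == g, ]
    per_night <- sapply(split(rows, rows$seed),
                        function(d) mean(d$distance_cm))
    i <- s2$strategy_class == g
    expect_equal(s2$mean_dist[i], mean(per_night))
    expect_equal(s2$n[i], 2)
  }
  # row order never matters
  shuffled <- out[rev(seq_len(nrow(out))), ]
  expect_equal(summarize_outcomes(shuffled, "strategy_class"), s2)
})

test_that("mated-only restriction and degenerate groups behave", {
  out <- fixture_outcomes()
  s <- summarize_outcomes(out, "strategy_class", mated_only_dist = TRUE,
                          unit = "female")
  rows <- out[out$strategy_class == "s_a", ]
  expect_equal(s$mean_dist[s$strategy_class == "s_a"],
               mean(rows$distance_cm[rows$mated]))
  # identical rows give a zero confidence half-width
  const <- out[out$strategy_class == "s_a", ]
  const$distance_cm <- 100
  expect_equal(summarize_outcomes(const, "strategy_class",
                                  unit = "female")$ci_dist, 0)
})

test_that("fitness follows the alpha-weighted convex combination", {
  p <- structure(list(alpha = 0.5, min_pn = 6, max_pn = 24,
                      min_dist = 100, max_dist = 1100),
                 class = "fitness_params")
  expect_equal(fitness(p, mean_pn = 15, mean_dist = 600), 0.5)
  # alpha = 0: only quality matters; top quality gives 1
  p0 <- p; p0$alpha <- 0
  expect_equal(fitness(p0, 24, 1e6), 1)
  # alpha = 1: only distance matters; minimal travel gives 1
  p1 <- p; p1$alpha <- 1
  expect_equal(fitness(p1, -50, 100), 1)
  # affine in alpha: midpoint of the endpoints
  f0 <- fitness(p0, 15, 600)
  f1 <- fitness(p1, 15, 600)
  expect_equal(fitness(p, 15, 600), (f0 + f1) / 2)
  # monotone: better mates raise it, longer travel lowers it
  expect_gt(fitness(p, 16, 600), fitness(p, 15, 600))
  expect_lt(fitness(p, 15, 700), fitness(p, 15, 600))
  bad <- p; bad$max_pn <- bad$min_pn
  expect_error(fitness(bad, 15, 600), "degenerate")
})

test_that("fitness extremes come from the whole outcome database", {
  out <- fixture_outcomes()
  p <- fitness_params(out, alpha = 0.3)
  expect_equal(p$min_pn, min(out$mate_pn[out$mated]))
  expect_equal(p$max_pn, max(out$mate_pn[out$mated]))
  expect_equal(p$min_dist, min(out$distance_cm))
  expect_equal(p$max_dist, max(out$distance_cm))
  fb <- fitness_by_class(out, alphas = c(0, 1))
  expect_equal(nrow(fb), 4)
  expect_true(all(fb$fitness >= 0 & fb$fitness <= 1))
})

test_that("Cohen's d matches its closed form", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(-1, 0, 1) + 1, c(-1, 0, 1)), 1)  # sd exactly 1
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
  a <- rnorm(50, 2, 3)
  b <- rnorm(40, 1, 2)
  sp <- sqrt((49 * var(a) + 39 * var(b)) / 88)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
})

test_that("the ANOVA report carries the design degrees of freedom", {
  out <- run_sweep(sweep_config(pop_means = c(12, 18),
                                n_females_list = c(5, 10),
                                replicates = 2, base_seed = 31))
  rep <- anova_report(out, "distance_cm")
  expect_equal(rep$df[rep$term == "sp"], 9)  # 10 strategy:parameter pairs
  expect_equal(rep$df[rep$term == "nf"], 1)
  expect_equal(rep$df[rep$term == "md"], 2)
  expect_true(all(c("sp:nf", "sp:md", "sp:nf:md:mp") %in% rep$term))
  # strategy differences in travel are overwhelming; noise factors are not
  expect_lt(rep$p_value[rep$term == "sp"], 1e-10)
  # shuffling the strategy labels destroys the main effect
  shuf <- out
  set.seed(1)
  shuf$strategy <- sample(shuf$strategy)
  rep2 <- anova_report(shuf, "distance_cm")
  expect_gt(rep2$p_value[rep2$term == "sp"], 1e-4)
  # single-level factors are dropped with a warning
  sub <- out[out$pop_mean == 12, ]
  expect_warning(anova_report(sub, "n_targets"), "single-level")
})
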