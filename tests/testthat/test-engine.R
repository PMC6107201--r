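test_that("move_toward never overshoots and converges in ceil(d/speed) cycles", {
  s <- move_toward(c(0, 0), c(0, 100), 10)
  expect_equal(s$position, c(0, 10))
  expect_equal(s$delta, 10)
  s <- move_toward(c(0, 97), c(0, 100), 10)
  expect_equal(s$position, c(0, 100))
  expect_equal(s$delta, 3)
  pos <- c(3, 4)
  target <- c(120, 90)
  d <- sqrt(sum((target - pos)^2))
  k <- 0
  while (!isTRUE(all.equal(pos, target))) {
    pos <- move_toward(pos, target, 7)$position
    k <- k + 1
  }
  expect_equal(k, ceiling(d / 7))
})

test_that("a lone female reaches a lone male by direct approach", {
  males <- make_males(0, 100, 12)
  females <- data.frame(id = 1, x = 0, y = 0)
  set.seed(1)
  out <- run_night(males, females, "best_of_n:1", speed = 10,
                   contact_radius = 5)
  expect_true(out$mated)
  expect_equal(out$mate_pn, 12L)
  expect_equal(out$cycles, 10)
  expect_equal(out$distance_cm, 100)
  expect_equal(out$n_targets, 1L)
})

test_that("two females converging on one male: exactly one mates per night", {
  males <- make_males(0, 0, 20)
  females <- data.frame(id = 1:2, x = c(0, 4), y = c(4, 0))
  set.seed(2)
  out <- run_night(males, females, "best_of_n:1", speed = 5)
  expect_equal(sum(out$mated), 1L)
  # the loser has no males left and is removed unmated
  expect_equal(sum(!out$mated), 1L)
})

test_that("min-threshold females with no acceptable male walk once and leave", {
  males <- make_males(c(100, 300), c(100, 300), c(10, 18))
  females <- data.frame(id = 1:3, x = c(0, 500, 900), y = c(0, 0, 0))
  set.seed(3)
  out <- run_night(males, females, "min_threshold:24", speed = 2)
  expect_true(all(!out$mated))
  expect_true(all(out$distance_cm == 2))
  expect_true(all(out$cycles == 1))
  expect_true(all(out$n_targets == 0))
})

test_that("identical configurations reproduce identical nights", {
  cfg <- sim_config("best_of_n:4", n_females = 15, distribution = "gaussian",
                    pop_mean = 18, seed = 77)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a, b)
  # the event log is a pure observer: outcomes unchanged
  c <- run_simulation(cfg, keep_log = TRUE)
  attr(c, "target_log") <- NULL
  expect_identical(a, c)
})

test_that("agents are conserved: each male and female mates at most once", {
  for (seed in c(5, 6, 7)) {
    out <- run_simulation(sim_config("best_of_n:5", n_females = 20,
                                     distribution = "random", pop_mean = 12,
                                     seed = seed))
    expect_lte(sum(out$mated), 20)
    mates <- out$mate_id[out$mated]
    expect_equal(anyDuplicated(mates), 0L)
    expect_true(all(out$cycles >= 1))
    expect_false(attr(out, "timed_out"))
    expect_lt(attr(out, "n_cycles"), 14400)
  }
})

test_that("retention strategies change target once per preemption event", {
  for (strategy in c("random", "min_threshold:6")) {
    out <- run_simulation(sim_config(strategy, n_females = 20,
                                     distribution = "random", pop_mean = 12,
                                     seed = 13), keep_log = TRUE)
    log <- attr(out, "target_log")
    expect_true(all(log$reason %in% c("initial", "target_mated")))
    events <- table(factor(log$female_id, levels = out$female_id))
    expect_equal(out$n_targets, as.integer(events))
    preempt <- table(factor(log$female_id[log$reason == "target_mated"],
                            levels = out$female_id))
    had_target <- out$n_targets > 0
    expect_equal(out$n_targets[had_target],
                 1L + as.integer(preempt)[had_target])
  }
})

test_that("best-of-n switches not forced by mating always trade up in quality", {
  for (seed in 101:110) {
    out <- run_simulation(sim_config("best_of_n:5", n_females = 20,
                                     distribution = "random", pop_mean = 12,
                                     seed = seed), keep_log = TRUE)
    log <- attr(out, "target_log")
    for (f in unique(log$female_id[log$reason == "better_male"])) {
      lf <- log[log$female_id == f, ]
      up <- which(lf$reason == "better_male")
      expect_true(all(lf$pulsenumber[up] > lf$pulsenumber[up - 1]))
    }
  }
})

test_that("a mated female's path is at least the straight-line distance", {
  set.seed(19)
  ch <- random_chorus(25, 15)
  set.seed(20)
  out <- run_night(ch$males, ch$females, "best_of_n:3")
  for (i in which(out$mated)) {
    straight <- sqrt((ch$males$x[out$mate_id[i]] - ch$females$x[i])^2 +
                       (ch$males$y[out$mate_id[i]] - ch$females$y[i])^2)
    expect_gte(out$distance_cm[i], straight - 5)  # contact radius slack
  }
})

test_that("the dynamics do not hide in the movement-rate constant", {
  # a lone female has no competition: halving speed must leave the mate
  # unchanged and the path equal up to one step of discretization
  set.seed(23)
  for (rep in 1:10) {
    ch <- random_chorus(25, 1)
    set.seed(1000 + rep)
    fast <- run_night(ch$males, ch$females, "best_of_n:3", speed = 2)
    set.seed(1000 + rep)
    slow <- run_night(ch$males, ch$females, "best_of_n:3", speed = 1)
    expect_equal(fast$mate_id, slow$mate_id)
    expect_lt(abs(fast$distance_cm - slow$distance_cm), 2)
  }
})

test_that("config validation rejects n beyond the chorus size", {
  expect_error(sim_config("best_of_n:30", n_females = 5,
                          distribution = "random", pop_mean = 12, seed = 1),
               "exceeds")
})
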