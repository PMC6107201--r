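# shared fixtures: all built in code at test time

# a deterministic male table for strategy-rule tests
make_males <- function(x, y, pn) {
  data.frame(id = seq_along(x), x = x, y = y, pulsenumber = as.integer(pn))
}

# random male/female states for property-style loops
random_chorus <- function(n_males = 25, n_females = 1, swamp = swamp_config()) {
  males <- sample_male_positions("random", n_males, 50, swamp)
  males$pulsenumber <- sample_pulsenumbers(12, 2, n_males)
  list(males = males, females = sample_female_positions(n_females, swamp))
}

# The desk-scale study sweep used by the acceptance tests: the full default
# factorial grid at 20 replicates per cell (9,600 nights), plus the
# no-switch best-of-n variant on the same grid (4,800 nights). Memoised so
# the several acceptance blocks share one computation.
.sweep_cache <- new.env(parent = emptyenv())

desk_sweep <- function() {
  if (is.null(.sweep_cache$main)) {
    .sweep_cache$main <- run_sweep(sweep_config(replicates = 20, base_seed = 20))
  }
  .sweep_cache$main
}

desk_sweep_no_switch <- function() {
  if (is.null(.sweep_cache$noswitch)) {
    .sweep_cache$noswitch <- run_sweep(
      sweep_config(strategies = paste0("best_of_n_no_switch:", 1:5),
                   replicates = 20, base_seed = 20))
  }
  .sweep_cache$noswitch
}
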