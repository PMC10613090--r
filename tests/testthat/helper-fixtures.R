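# Shared synthetic cohorts, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, maker(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Study-sized cohort (n = 2750) with the default availability pattern.
study_cohort <- function() {
  fixture("study", function() simulate_study_cohort(sim_config(seed = 101)))
}

# Large fully observed cohort for parameter-recovery checks.
big_cohort <- function() {
  fixture("big", function() {
    generate_cohort(sim_config(n_records = 20000, seed = 202))
  })
}

# Small fully observed cohort for cheap pipeline checks.
small_cohort <- function() {
  fixture("small", function() {
    generate_cohort(sim_config(n_records = 600, seed = 303))
  })
}
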