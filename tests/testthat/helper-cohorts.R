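# Cohort fixtures built in code.

small_cohort <- function(seed = 11, n_per_group = 6) {
  simulate_cohort(default_synthetic_config(n_per_group = n_per_group),
                  seed = seed)
}

paper_scale_cohort <- function(seed = 1) {
  simulate_cohort(default_synthetic_config(), seed = seed)
}
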