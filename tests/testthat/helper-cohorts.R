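# Single-branch cohort specs: the measured-GFR range and age bounds are
# chosen so that every generated creatinine stays on the generating branch
# of the piecewise equation (needed for exact-inversion and
# parameter-recovery checks).  The ranges keep a >= 4-sigma margin from
# the creatinine threshold at noise_sigma = 0.15, so threshold crossings
# that would contaminate a branch are vanishingly rare.

branch_spec <- function(branch = c("female_low", "female_high",
                                   "male_low", "male_high"),
                        n = 500, noise_sigma = 0, seed = 1,
                        age_coupled = TRUE) {
  branch <- match.arg(branch)
  tab <- gfr_branches()
  cfg <- switch(branch,
    female_low  = list(row = 1, male = 0, edges = c(115, 126, 137, 148, 159, 170)),
    female_high = list(row = 2, male = 0, edges = c(12, 16, 20, 24, 29, 33)),
    male_low    = list(row = 3, male = 1, edges = c(122, 132, 142, 151, 161, 170)),
    male_high   = list(row = 4, male = 1, edges = c(12, 17, 22, 27, 32, 36)))
  b <- tab[cfg$row, ]
  gen <- data.frame(sex = c("female", "male"),
                    threshold = c(1.2, 1.0),
                    scale = b$scale, exponent = b$exponent,
                    age_base = b$age_base)
  cohort_spec(n = n, stage_props = rep(0.2, 5), stage_edges = cfg$edges,
              age_mean = 55, age_sd = 15, age_range = c(18, 90),
              male_fraction = cfg$male, diabetes_fraction = 0.3,
              gen_coefficients = gen, age_coupled = age_coupled,
              noise_sigma = noise_sigma, seed = seed,
              label = paste0("branch_", branch))
}

branch_truth <- function(branch) {
  row <- switch(branch, female_low = 1, female_high = 2,
                male_low = 3, male_high = 4)
  gfr_branches()[row, ]
}

tiny_cohort <- function(n = 6) {
  data.frame(id = paste0("p", seq_len(n)),
             age = seq(30, 30 + 5 * (n - 1), by = 5),
             sex = rep(c("female", "male"), length.out = n),
             scr = seq(0.8, 0.8 + 0.4 * (n - 1), by = 0.4),
             mgfr = seq(80, 80 - 8 * (n - 1), by = -8))
}
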