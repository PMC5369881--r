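# Simulation helpers shared across test files.

# Cohort whose case/control log-score difference lies exactly along the
# (1, -1, 0.5) exponent direction: markers are drawn with a wide
# free-to-total ratio (Beta(2, 2)) and dispersed tPSA so all three log
# markers carry identifiable variation, and labels follow a logistic law
# in s = log(tpsa) - log(fpsa) + 0.5 log(cpsa).  Equal-sized groups are
# subsampled case-control style (which only shifts the intercept).
sim_truth_cohort <- function(n_per_group, k = 3, seed = 1) {
  set.seed(seed)
  N <- 10 * n_per_group
  t <- exp(rnorm(N, log(6), 0.8))
  r <- rbeta(N, 2, 2)
  f <- r * t
  cc <- t - f
  s <- log(t) - log(f) + 0.5 * log(cc)
  y <- rbinom(N, 1, plogis(k * (s - mean(s))))
  idx <- c(sample(which(y == 1), n_per_group),
           sample(which(y == 0), n_per_group))
  data.frame(diagnosis = ifelse(y[idx] == 1, "PCa", "BPH"),
             tpsa = t[idx], fpsa = f[idx], cpsa = cc[idx])
}

# Small hand-checkable cohort with exact marker triplets.
tiny_cohort <- function() {
  data.frame(
    id = sprintf("T%02d", 1:6),
    age = c(65, 70, 72, 68, 75, 71),
    diagnosis = c("PCa", "PCa", "PCa", "BPH", "BPH", "BPH"),
    tpsa = c(8, 6, 12, 4, 5, 11),
    fpsa = c(1, 1.2, 1.5, 1, 1.1, 2),
    cpsa = c(7, 4.8, 10.5, 3, 3.9, 9)
  )
}

# Random marker triplets satisfying the record invariants.
random_triplets <- function(n, seed = 1) {
  set.seed(seed)
  t <- runif(n, 2, 20)
  r <- runif(n, 0.02, 0.6)
  data.frame(tpsa = t, fpsa = r * t, cpsa = t * (1 - r))
}
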