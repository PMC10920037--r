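# Shared fixtures, built once per test run. The "study" cohort uses the
# default five-class catalog at reduced noise (the separable regime the
# recovery properties are stated for); heavier objects are memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, .fixture_env)
}

low_noise_spec <- function(n = 500, seed = 11) {
  cohort_spec(n_participants = n, within_class_sd = 0.25,
              random_intercept_sd = 0.1, seed = seed)
}

study_cohort <- function() {
  memo("study_cohort", function() generate_cohort(low_noise_spec()))
}

study_tensor <- function() {
  memo("study_tensor", function() standardize(study_cohort()$scale_table))
}

# small hand-specified tensor: n participants, T waves, D assessments
toy_tensor <- function(n = 6, tt = 3, d = 2, seed = 5, miss = 0) {
  set.seed(seed)
  v <- array(stats::rnorm(n * tt * d), dim = c(n, tt, d))
  m <- array(1, dim = dim(v))
  if (miss > 0) {
    drop <- stats::runif(length(v)) < miss
    v[drop] <- NA
    m[drop] <- 0
  }
  structure(list(values = v, mask = m, participant_ids = seq_len(n),
                 wave_labels = paste0("T", seq_len(tt)),
                 assessment_names = paste0("a", seq_len(d))),
            class = "trajectory_tensor")
}

# closed-form KL between diagonal Gaussians, independent of the model code
kl_diag_oracle <- function(mu_q, s2_q, mu_p, s2_p) {
  0.5 * sum(log(s2_p / s2_q) + (s2_q + (mu_q - mu_p)^2) / s2_p - 1)
}
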