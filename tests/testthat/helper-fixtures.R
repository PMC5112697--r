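# Small fixtures built in code; every test draws from here.

# Two tight, far-apart clusters: nothing should ever be edited away.
# One feature dimension on purpose: after z-scoring, pure-noise dimensions
# always come out with unit spread, which would erode the margin.
separable_dataset <- function(subjects_per_class = 5, samples_per_subject = 6,
                              d = 1, seed = 3) {
  generate_synthetic(synthetic_config(
    subjects_per_class = subjects_per_class,
    samples_per_subject = samples_per_subject, d = d,
    delta_sep = 20, sigma_subj = 0.15, sigma_noise = 0.3, rho = 0,
    seed = seed))
}

# Moderate-difficulty subject-clustered data for protocol tests.
small_mixed_dataset <- function(seed = 11, rho = 0) {
  generate_synthetic(synthetic_config(
    subjects_per_class = 4, samples_per_subject = 6, d = 4,
    delta_sep = 3, sigma_subj = 1, sigma_noise = 1, rho = rho,
    seed = seed))
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# layout for the 4-column toy rows "id,f1,f2,label"
toy_layout <- function() sakar_layout(id_col = 1, feature_cols = 2:3,
                                      label_col = 4)
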