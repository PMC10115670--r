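# Shared fixtures: a small acquisition geometry keeps unit tests fast while
# preserving the depth constraints of the full geometry.

small_acq <- function(site = "lumbar", noise_sd = 0.3, n_lines = 16L) {
  acquisition_params(site, n_lines = n_lines, samples_per_line = 1024L,
                     noise_sd = noise_sd)
}

# Tiny reference database: one or more strata, built through the full
# pipeline on a reduced geometry.
small_db <- function(strata = data.frame(sex = "F", age_bin = "60-64",
                                         bmi_class = "normal", site = "lumbar",
                                         stringsAsFactors = FALSE),
                     templates = spectral_templates(),
                     n_per_category = 10L, seed = 11L, noise_sd = 0.3) {
  build_reference_database(strata, n_per_category = n_per_category,
                           seed = seed, templates = templates,
                           acq = small_acq(strata$site[1], noise_sd = noise_sd))
}

small_profile <- function(f = 0.5, sex = "F", age = 62, bmi = 24) {
  list(id = "t1", sex = sex, age = age, bmi = bmi, f_latent = f)
}

# Independent AUC oracle: concordance over all (positive, negative) pairs,
# ties counted one half.
auc_pair_counting <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
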