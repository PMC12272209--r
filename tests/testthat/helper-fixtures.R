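# shared fixtures and small builders for the test suite

toy_spec <- function(outcome, fixed, group = "subj_id",
                     interest_term = fixed[1], sign = 1) {
  structure(list(name = "toy", outcome = outcome, fixed = fixed,
                 group = group, bp_source = "dbp",
                 interest = data.frame(term = interest_term, sign = sign)),
            class = "wmh_model_spec")
}

# effect configuration with every longitudinal effect and noise source off
null_effects <- function(whr_scale = 1, ...) {
  effect_config(whr_scale = whr_scale,
                time_mean = 0, time_sd = 0,
                bp_base_mod_mean = 0, bp_base_mod_sd = 0,
                bp_change_eff_mean = 0, bp_change_eff_sd = 0,
                whr_base_modifier = 0, whr_change_effect = 0,
                random_intercept_sd = 0, residual_sd = 0, ...)
}

# all longitudinal effects off, observation noise kept
null_effects_noisy <- function(whr_scale = 1) {
  effect_config(whr_scale = whr_scale,
                time_mean = 0, time_sd = 0,
                bp_base_mod_mean = 0, bp_base_mod_sd = 0,
                bp_change_eff_mean = 0, bp_change_eff_sd = 0,
                whr_base_modifier = 0, whr_change_effect = 0)
}

noise_free_link <- function(beta = -0.149, seed = 1) {
  cognition_link_config(
    wmh_change_beta = beta, seed = seed,
    test_noise_sd = c(tmt_a = 0, ratio = 0, fluency_phon = 0,
                      fluency_sem = 0, wl_learning = 0, wl_recall = 0,
                      wl_recognition = 0))
}

# normalized interaction label (R reorders interaction factors)
norm_term <- function(s) {
  vapply(strsplit(s, ":", fixed = TRUE), function(p) {
    p <- sub("^gender(male|female)$", "gender", p)
    paste(sort(p), collapse = ":")
  }, "")
}

coef_row <- function(fit, term) {
  ct <- fit$coefficients
  ct[norm_term(ct$term) == norm_term(term), , drop = FALSE]
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(cohort_config(80, seed = 421))
    cache
  }
})
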