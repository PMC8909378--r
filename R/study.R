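# Desk-scale end-to-end study: the full chain (phantom cohort ->
# preprocessing -> stage-two-shaped ensemble -> held-out pooled Dice) at
# sizes a single CPU handles in minutes. Network widths 4/8 stand in for
# the study-scale 32/64; everything else (slice filter, logit-sum fusion,
# patient-level held-out split, global Dice) is the full pipeline.

#' Run the scaled-down end-to-end recovery study
#'
#' Generates a phantom cohort, holds out `n_test` patients, trains the
#' six-member stage-two-shaped ensemble (losses WCE/DC/LV crossed with two
#' widths) on the pathology-filtered slices of the development patients,
#' and reports pooled global Dice on every scan of the held-out patients.
#'
#' @param seed governs cohort generation, initialisation and shuffling.
#' @param n_patients cohort size (default 6).
#' @param n_test held-out patients (default 2).
#' @param base_filters the two ensemble widths (default `c(4, 8)`).
#' @param target network input `(rows, cols)`; default `c(48, 80)` fits the
#'   default phantom grid at original resolution.
#' @param epochs,lr,slice_cap training schedule: passes over the training
#'   set, Adam rate, and the per-volume cap on filtered slices (evenly
#'   spaced) that keeps the sample count desk-scale.
#' @return List: `dice` (held-out per-class global Dice), `report` (full
#'   `eval_report`), `frequencies` (all-slices cohort class fractions),
#'   `frequencies_filtered`, `n_train_samples`.
#' @export
scaled_down_study <- function(seed = 1L, n_patients = 6L, n_test = 2L,
                              base_filters = c(4L, 8L),
                              target = c(48L, 80L), epochs = 8L, lr = 1e-2,
                              slice_cap = 6L) {
  spec <- phantom_spec(n_patients = n_patients, seed = seed)
  cases <- generate_cohort(spec)$cases
  patients <- unique(vapply(cases, `[[`, character(1), "patient"))
  split <- fixed_split(patients, n_test = n_test, seed = seed)
  train_cases <- Filter(function(cs) cs$patient %in% split$dev, cases)
  test_cases <- Filter(function(cs) cs$patient %in% split$test, cases)

  samples <- unlist(lapply(train_cases, function(cs) {
    pl <- slice_plan(cs, target = target)
    ret <- pl$retained
    if (length(ret) > slice_cap)
      ret <- ret[round(seq(1, length(ret), length.out = slice_cap))]
    make_samples(cs, pl, slices = ret)
  }), recursive = FALSE)

  freqs_all <- class_frequencies(cases, "all")
  freqs_flt <- class_frequencies(train_cases, "filtered")
  weights <- weights_from_frequencies(freqs_flt)
  configs <- ensemble_config("stage2", base_filters = base_filters,
                             seed = seed)
  nets <- train_ensemble(configs, samples, weights = weights,
                         epochs = epochs, lr = lr, seed = seed)
  report <- evaluate_cases(nets, test_cases, target = target)
  list(dice = report$dice, report = report,
       frequencies = freqs_all, frequencies_filtered = freqs_flt,
       n_train_samples = length(samples))
}
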