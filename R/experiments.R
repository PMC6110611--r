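#' Read and write trial tables
#'
#' Trial data travel as tab-separated text with a header and columns
#' `subject`, `set_size`, `p_probe`, `error_rad`, `condition_tag` (errors in
#' radians on `[-pi, pi)`). `write_trials()` also emits a YAML sidecar
#' manifest (same path with extension `.meta.yaml`) recording the generator
#' settings when the table came from [generate_trials()].
#'
#' @param data Trial tibble.
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns `path`
#'   invisibly.
#' @export
write_trials <- function(data, path) {
  check_trial_data(data)
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gen <- attr(data, "generator")
  if (!is.null(gen) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(gen, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_trial_data(tibble::as_tibble(df))
}

#' Simulate a full experiment to disk or memory
#'
#' Thin wrapper around [builtin_design()] and [generate_trials()] that
#' simulates one or more subjects and optionally writes one trial table per
#' subject plus a manifest.
#'
#' @param design Design name (`"E1"`-`"E9"`) or a design tibble.
#' @param policy An [allocation_policy()].
#' @param params A [model_params()].
#' @param n_subjects Number of simulated subjects.
#' @param n_per_condition Trials per condition and subject.
#' @param seed Base seed; subject s uses `seed + s - 1`.
#' @param out_dir Optional output directory for `.tsv` tables.
#' @return A tibble of all trials (all subjects bound together).
#' @export
simulate_experiment <- function(design, policy, params, n_subjects = 1,
                                n_per_condition = 200, seed = 1L,
                                out_dir = NULL) {
  if (is.character(design)) design <- builtin_design(design)
  tabs <- lapply(seq_len(n_subjects), function(s) {
    d <- generate_trials(design, policy, params,
                         n_per_condition = n_per_condition,
                         seed = seed + s - 1L,
                         subject = sprintf("S%02d", s))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_trials(d, file.path(out_dir, sprintf("trials_S%02d.tsv", s)))
    }
    d
  })
  dplyr::bind_rows(tabs)
}

#' Fit several models to each subject and compare them
#'
#' Fits every model in `models` to every subject in `data`, optionally adds
#' interleaved five-fold cross-validation, and returns the per-subject
#' comparison table (see [aic_compare()]; the first model is the reference).
#'
#' @param data Trial tibble (may contain several subjects).
#' @param models Named list of [model_spec()]s; the first is the reference.
#' @param cv Add five-fold cross-validated log likelihoods.
#' @param seed Seed passed to the fits.
#' @param control A [fit_control()].
#' @return A list with `fits` (nested named list by subject) and
#'   `comparison` (tibble with a `subject` column).
#' @export
fit_models <- function(data, models, cv = FALSE, seed = 1L,
                       control = fit_control()) {
  check_trial_data(data)
  stopifnot(is.list(models), !is.null(names(models)))
  if (!"subject" %in% names(data)) data$subject <- "S1"
  subjects <- unique(data$subject)
  all_fits <- lapply(subjects, function(sj) {
    d <- data[data$subject == sj, , drop = FALSE]
    fits <- lapply(models, function(m) {
      f <- fit_mle(d, m, seed = seed, control = control)
      if (cv) f <- crossval_5fold(d, m, seed = seed, control = control,
                                  fit = f)
      f
    })
    fits
  })
  names(all_fits) <- subjects
  comparison <- dplyr::bind_rows(lapply(subjects, function(sj) {
    dplyr::mutate(aic_compare(all_fits[[sj]]), subject = sj,
                  .before = 1)
  }))
  list(fits = all_fits, comparison = comparison)
}

#' Theory curves: optimal resource and cost decomposition
#'
#' `theory_resource_curve()` tabulates the optimal per-item resource against
#' probing probability; `theory_cost_decomposition()` tabulates the expected
#' behavioral, neural, and total cost per item against invested resource for
#' a set of probing probabilities; `theory_feedback_sweep()` sweeps the
#' binary-feedback threshold and reports the optimal resource and resulting
#' expected absolute error (flat at `pi/2` wherever encoding nothing is
#' optimal).
#'
#' @param params A [model_params()].
#' @param p_grid Probing probabilities.
#' @param j_grid Resource grid for the decomposition.
#' @param thresholds Feedback thresholds in radians.
#' @param ... Passed to [optimal_resource()].
#' @return A tibble.
#' @export
theory_resource_curve <- function(params, p_grid = seq(0.05, 1, by = 0.05),
                                  ...) {
  tibble::tibble(p = p_grid,
                 j_opt = optimal_resource(p_grid, params, ...))
}

#' @rdname theory_resource_curve
#' @export
theory_cost_decomposition <- function(params,
                                      p_grid = c(1, 1 / 2, 1 / 4, 1 / 8),
                                      j_grid = seq(0, 40, length.out = 81)) {
  cb <- expected_behavioral_cost(j_grid, params$tau, params$cost)
  purrr::map_dfr(p_grid, function(p) {
    tibble::tibble(p = p, j_bar = j_grid,
                   behavioral = p * cb,
                   neural = params$lambda * j_grid,
                   total = p * cb + params$lambda * j_grid)
  })
}

#' @rdname theory_resource_curve
#' @param p Probing probability for the feedback sweep (display of N items
#'   with equal probabilities has `p = 1/N`).
#' @export
theory_feedback_sweep <- function(params,
                                  thresholds = seq(0.05, pi - 0.05,
                                                   length.out = 25),
                                  p = 1 / 5, ...) {
  abs_cost <- cost_spec("abs")
  purrr::map_dfr(thresholds, function(th) {
    pars <- model_params(params$lambda, params$tau,
                         cost_spec("binary_threshold", threshold = th))
    jo <- optimal_resource(p, pars, ...)
    tibble::tibble(
      threshold = th, j_opt = jo,
      expected_abs_error = expected_behavioral_cost(jo, params$tau, abs_cost)
    )
  })
}
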