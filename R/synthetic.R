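#' Built-in delayed-estimation designs
#'
#' Display structures of nine published delayed-estimation experiments,
#' identified as E1-E9:
#'
#' * E1 (color): set sizes 1, 2, 4, 8; equal probing probability.
#' * E2 (color): set sizes 1, 2, 3, 6; equal.
#' * E3 (color): set sizes 1, 2, 4, 6; equal.
#' * E4 (orientation), E5 (color wheel), E6 (color scroll): set sizes 1-8;
#'   equal.
#' * E7 (orientation): set sizes 2, 4, 8 with a 3:1 cue — probing
#'   probabilities (3/4, 1/4) at N = 2, (1/2, 1/6, 1/6, 1/6) at N = 4, and
#'   (3/10, 1/10 x 7) at N = 8.
#' * E8 (color, N = 4) and E9 (color, N = 6): cue-validity designs whose
#'   unique probing probabilities are {1/6, 2/9, 1/4, 1/3, 1/2, 1} and
#'   {1/12, 1/10, 2/15, 1/6, 1/3, 1/2, 1}. Conditions are generated directly
#'   from these unique values (one condition per value; the probed item
#'   always carries it); p = 0 items are never probed and contribute no
#'   trials, so they are not represented.
#'
#' @param name One of `"E1"` to `"E9"`.
#' @return A tibble of class `display_design` with columns `condition_tag`,
#'   `set_size` and `p_items` (list-column of per-item probing
#'   probabilities).
#' @export
#' @examples
#' builtin_design("E7")
builtin_design <- function(name) {
  designs <- list(
    E1 = list(feature = "color", equal = c(1, 2, 4, 8)),
    E2 = list(feature = "color", equal = c(1, 2, 3, 6)),
    E3 = list(feature = "color", equal = c(1, 2, 4, 6)),
    E4 = list(feature = "orientation", equal = 1:8),
    E5 = list(feature = "color", equal = 1:8),
    E6 = list(feature = "color", equal = 1:8),
    E7 = list(feature = "orientation", cued = list(
      list(set_size = 2, p = c(3 / 4, 1 / 4)),
      list(set_size = 4, p = c(1 / 2, rep(1 / 6, 3))),
      list(set_size = 8, p = c(3 / 10, rep(1 / 10, 7)))
    )),
    E8 = list(feature = "color",
              unique_p = c(1 / 6, 2 / 9, 1 / 4, 1 / 3, 1 / 2, 1),
              set_size = 4),
    E9 = list(feature = "color",
              unique_p = c(1 / 12, 1 / 10, 2 / 15, 1 / 6, 1 / 3, 1 / 2, 1),
              set_size = 6)
  )
  if (!name %in% names(designs)) {
    stop("unknown design '", name, "'; use one of ",
         paste(names(designs), collapse = ", "), call. = FALSE)
  }
  d <- designs[[name]]
  out <- if (!is.null(d$equal)) {
    tibble::tibble(
      condition_tag = paste0("N", d$equal),
      set_size = as.integer(d$equal),
      p_items = lapply(d$equal, function(n) rep(1 / n, n))
    )
  } else if (!is.null(d$cued)) {
    tibble::tibble(
      condition_tag = paste0("N", vapply(d$cued, `[[`, numeric(1), "set_size")),
      set_size = as.integer(vapply(d$cued, `[[`, numeric(1), "set_size")),
      p_items = lapply(d$cued, `[[`, "p")
    )
  } else {
    tibble::tibble(
      condition_tag = paste0("p", signif(d$unique_p, 4)),
      set_size = as.integer(rep(d$set_size, length(d$unique_p))),
      p_items = lapply(d$unique_p, function(p) rep(p, d$set_size))
    )
  }
  attr(out, "design_name") <- name
  attr(out, "feature") <- d$feature
  class(out) <- c("display_design", class(out))
  out
}

#' Generate synthetic delayed-estimation trials
#'
#' Draws trial-level data from the generative side of the model: for each
#' condition the allocation policy assigns a mean precision to every item;
#' on each trial the probed item is drawn with probability proportional to
#' its probing probability (items with p = 0 are never probed), its realized
#' precision is gamma-distributed with mean `j_bar` and scale `tau`, and the
#' estimation error is Von Mises with the matching concentration. Identical
#' inputs and seed give identical tables.
#'
#' @param design A `display_design` (see [builtin_design()]) or a tibble with
#'   columns `condition_tag`, `set_size`, `p_items`.
#' @param policy An [allocation_policy()].
#' @param params A [model_params()] (`tau` governs the precision
#'   variability; the rational policy also uses `lambda` and the cost).
#' @param n_per_condition Trials per design condition (default 200, the
#'   hundreds-scale typical of these experiments).
#' @param seed Integer seed.
#' @param subject Subject label stored in the table.
#' @return A tibble with columns `subject`, `trial`, `condition_tag`,
#'   `set_size`, `p_probe`, `error_rad`, plus attributes recording the seed
#'   and generator settings.
#' @export
#' @examples
#' d <- generate_trials(builtin_design("E1"),
#'                      allocation_policy("fixed_equal", j_total = 30),
#'                      model_params(0.01, 5), n_per_condition = 10, seed = 1)
#' head(d)
generate_trials <- function(design, policy, params,
                            n_per_condition = 200, seed = 1L,
                            subject = "S1") {
  stopifnot(is.data.frame(design),
            all(c("condition_tag", "set_size", "p_items") %in% names(design)),
            inherits(policy, "allocation_policy"),
            inherits(params, "model_params"))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    pv <- design$p_items[[i]]
    jv <- allocate_display(pv, policy, params)
    probeable <- which(pv > 0)
    if (length(probeable) == 0) return(NULL)
    pick <- probeable[sample.int(length(probeable), n_per_condition,
                                 replace = TRUE, prob = pv[probeable])]
    j_bar <- jv[pick]
    j <- if (params$tau < .rrvwm$tau_floor) j_bar else {
      ifelse(j_bar > 0,
             rgamma(n_per_condition, shape = j_bar / params$tau,
                    scale = params$tau),
             0)
    }
    err <- ifelse(is.infinite(j), 0, r_vm(n_per_condition, j_to_kappa(
      pmin(ifelse(is.finite(j), j, 0), 1e12))))
    tibble::tibble(
      condition_tag = design$condition_tag[i],
      set_size = design$set_size[i],
      p_probe = pv[pick],
      error_rad = err
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::tibble(subject = subject,
                        trial = seq_len(nrow(out)), out)
  attr(out, "generator") <- list(policy = policy$kind, seed = seed,
                                 tau = params$tau,
                                 n_per_condition = n_per_condition)
  out
}

#' Parameter- and model-recovery harness
#'
#' Runs the full simulate-and-refit loop: for each seed, trials are generated
#' under a known policy and parameters, every candidate model is fitted, and
#' the harness reports recovered parameters with relative errors plus an
#' AIC-based confusion row (which candidate won). Deterministic given the
#' seed vector.
#'
#' @param design A display design (see [builtin_design()]).
#' @param policy Generating [allocation_policy()].
#' @param params Generating [model_params()].
#' @param fit_models Named list of [model_spec()] candidates to fit.
#' @param seeds Integer vector of seeds (one synthetic subject per seed).
#' @param n_per_condition Trials per condition per subject.
#' @param control A [fit_control()].
#' @param true_theta Optional named vector of generating parameter values on
#'   the fitted scale, used for the relative-error report.
#' @return A list with `fits` (tibble: seed, model, loglik, aic, winner flag)
#'   and `recovery` (tibble of true vs recovered parameters, when
#'   `true_theta` is supplied and the matching model is among the
#'   candidates).
#' @export
recovery_harness <- function(design, policy, params, fit_models, seeds,
                             n_per_condition = 200,
                             control = fit_control(), true_theta = NULL) {
  stopifnot(is.list(fit_models), !is.null(names(fit_models)))
  res <- lapply(seeds, function(sd) {
    dat <- generate_trials(design, policy, params,
                           n_per_condition = n_per_condition, seed = sd)
    fits <- lapply(fit_models, function(m) {
      fit_mle(dat, m, seed = sd, control = control)
    })
    gl <- purrr::imap_dfr(fits, function(f, nm) {
      tibble::tibble(seed = sd, model = nm, loglik = f$loglik,
                     n_params = f$n_params, aic = f$aic)
    })
    gl$winner <- gl$aic == min(gl$aic)
    list(glance = gl, fits = fits)
  })
  fits_tbl <- dplyr::bind_rows(lapply(res, `[[`, "glance"))
  recovery <- NULL
  if (!is.null(true_theta)) {
    gen_kind <- if (policy$kind == "rational") "rational" else policy$kind
    hit <- which(vapply(fit_models, function(m) m$kind == gen_kind, logical(1)))
    if (length(hit)) {
      recovery <- dplyr::bind_rows(lapply(seq_along(seeds), function(i) {
        th <- res[[i]]$fits[[hit[1]]]$theta
        common <- intersect(names(true_theta), names(th))
        tibble::tibble(seed = seeds[i], term = common,
                       true = unname(true_theta[common]),
                       estimate = unname(th[common]),
                       rel_error = abs(unname(th[common]) -
                                         unname(true_theta[common])) /
                         abs(unname(true_theta[common])))
      }))
    }
  }
  list(fits = fits_tbl, recovery = recovery)
}
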