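# Validation experiments for the model-fitting procedure, run against the
# synthetic generator: known-process single-fit recovery, random-uniform null
# safety, and mixture support/ranking recovery. These are the package-level
# analogues of fitting known experimental distributions before trusting the
# archaeological fits.

#' Known-process single-best-fit recovery experiment
#'
#' For each seed, draws a fresh replicate assemblage of a held-out process at
#' its default (experimental) sample size and fits it against the expected
#' distribution curves of all candidate processes; scores how often the
#' generating process is returned as the single best fit. The default
#' held-out process is the armature profile, the validation design used when
#' the method was introduced (an independent armature sample fitted by the
#' armature model); pass several `processes` to cycle through them.
#'
#' @param n_seeds number of replicates.
#' @param seed master seed.
#' @param profiles profile list (default [default_process_profiles()]).
#' @param candidates candidate process names (default the four general
#'   processes).
#' @param processes held-out process name(s), cycled across seeds.
#' @param alpha loess span.
#' @return list with `rate` (percent recovered), `n`, and a `detail` data
#'   frame (process, selected, hit).
#' @export
validate_single_recovery <- function(n_seeds = 100L, seed = 1L,
                                     profiles = default_process_profiles(),
                                     candidates = general_process_names(),
                                     processes = "armature_quartzite",
                                     alpha = 0.15) {
  refs <- lapply(profiles[candidates], profile_expected_distribution, alpha = alpha)
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    pn <- processes[((s - 1L) %% length(processes)) + 1L]
    rep_d <- sample_process_distribution(profiles[[pn]],
                                         seed = seed * 10000L + s,
                                         alpha = alpha)$distribution
    f <- fit_single_best(candidates_from_distributions(rep_d, refs))
    rows[[s]] <- data.frame(process = pn, selected = f$terms,
                            r_squared = f$r_squared,
                            hit = identical(f$terms, pn),
                            stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, rows)
  list(rate = 100 * mean(detail$hit), n = n_seeds, detail = detail)
}

#' Random-uniform null-safety experiment
#'
#' Fits random uniform damage distributions (positions drawn with
#' replacement) against the candidate process curves and records the single
#' best-fit R-squared; a sound procedure should explain almost none of the
#' variability of random patterning.
#'
#' @param n_draws draws per replicate (reference size 10000).
#' @param n_rep replicates.
#' @param seed master seed.
#' @param profiles,candidates,alpha as in [validate_single_recovery()].
#' @return list with `r_squared` vector, `median_r2` and `mean_r2`.
#' @export
validate_random_uniform <- function(n_draws = 10000L, n_rep = 20L, seed = 1L,
                                    profiles = default_process_profiles(),
                                    candidates = general_process_names(),
                                    alpha = 0.15) {
  refs <- lapply(profiles[candidates], profile_expected_distribution, alpha = alpha)
  r2 <- vapply(seq_len(n_rep), function(i) {
    d <- random_uniform_distribution(n_draws, seed = seed * 20000L + i, alpha = alpha)
    fit_single_best(candidates_from_distributions(d, refs))$r_squared
  }, 0)
  list(r_squared = r2, median_r2 = stats::median(r2), mean_r2 = mean(r2))
}

#' Mixture support- and ranking-recovery experiment
#'
#' Generates assemblages from known mixtures of one to three processes
#' (weights 1; 0.6/0.4; 0.5/0.3/0.2), runs the forward-stepwise fit against
#' all candidate curves, and scores (a) exact recovery of the true support
#' and (b) agreement of the contribution ranking of the true terms with the
#' weight ranking (scored whenever every true term is selected).
#'
#' @param n_rep number of replicates (component counts are cycled 1, 2, 3).
#' @param n_tools tools per mixture assemblage.
#' @param seed master seed.
#' @param profiles,candidates,alpha as in [validate_single_recovery()].
#' @return list with `support_rate` and `ranking_rate` (percents), and a
#'   `detail` data frame.
#' @export
validate_mixture_recovery <- function(n_rep = 200L, n_tools = 150L, seed = 1L,
                                      profiles = default_process_profiles(),
                                      candidates = general_process_names(),
                                      alpha = 0.15) {
  refs <- lapply(profiles[candidates], profile_expected_distribution, alpha = alpha)
  rows <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    k <- ((i - 1L) %% 3L) + 1L
    set.seed(seed * 30000L + i)
    comps <- sample(candidates, k)
    w <- stats::setNames(switch(k, 1, c(0.6, 0.4), c(0.5, 0.3, 0.2)), comps)
    mix <- generate_mixture(mixture_spec(w, n_tools, seed = seed * 30000L + i),
                            profiles, alpha = alpha)
    f <- suppressWarnings(forward_stepwise(
      candidates_from_distributions(mix$distribution, refs)))
    support_ok <- setequal(f$terms, comps)
    all_in <- all(comps %in% f$terms)
    ranking_ok <- all_in &&
      identical(names(sort(f$contributions[comps], decreasing = TRUE)),
                names(sort(w, decreasing = TRUE)))
    rows[[i]] <- data.frame(k = k, true = paste(sort(comps), collapse = "+"),
                            selected = paste(sort(f$terms), collapse = "+"),
                            support_ok = support_ok, ranking_ok = ranking_ok,
                            stringsAsFactors = FALSE)
  }
  detail <- do.call(rbind, rows)
  list(support_rate = 100 * mean(detail$support_ok),
       ranking_rate = 100 * mean(detail$ranking_ok),
       n = n_rep, detail = detail)
}
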