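#' Small-sample-corrected Akaike information criterion
#'
#' AICc for an ordinary least squares fit with residual sum of squares `rss`
#' on `n` observations and `k` estimated parameters:
#' `n * log(rss / n) + 2k + 2k(k + 1) / (n - k - 1)`. By the counting
#' convention used throughout the package, `k` includes the regression
#' coefficients (intercept plus terms) and one parameter for the error
#' variance.
#'
#' @param rss positive residual sum of squares.
#' @param n number of observations; must exceed `k + 1` or the correction
#'   term is undefined.
#' @param k parameter count.
#' @return AICc value.
#' @export
aicc <- function(rss, n, k) {
  if (rss <= 0) stop("rss must be positive")
  if (n <= k + 1) stop("n must exceed k + 1 for the small-sample correction")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Bundle a response distribution with candidate process predictors
#'
#' @param response numeric series (e.g. an archaeological distribution's raw
#'   proportions over the 400 standardized positions).
#' @param predictors named list or matrix of candidate series (experimental
#'   process distributions, usually loess-smoothed proportions), all the same
#'   length as the response.
#' @param response_label name used in reports.
#' @return an `edd_candidates` object.
#' @export
candidate_set <- function(response, predictors, response_label = "response") {
  y <- as.numeric(response)
  if (is.list(predictors)) {
    nm <- names(predictors)
    predictors <- do.call(cbind, lapply(predictors, as.numeric))
    colnames(predictors) <- nm
  }
  X <- as.matrix(predictors)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("predictors must have unique names")
  }
  if (nrow(X) != length(y)) stop("response and predictors must have equal length")
  if (any(!is.finite(y)) || any(!is.finite(X))) stop("missing/non-finite values not allowed")
  structure(list(response = y, predictors = X, n = length(y),
                 response_label = response_label),
            class = "edd_candidates")
}

#' Build a candidate set from assemblage distributions
#'
#' The canonical comparison scale is proportions, so that assemblages of
#' different sizes are comparable: the response enters as raw proportions and
#' each candidate as its loess-smoothed proportion curve (both switchable).
#'
#' @param response_dist `edd_distribution` to be explained.
#' @param predictor_dists named list of `edd_distribution` candidates.
#' @param smooth_response,smooth_predictors use the smoothed series instead
#'   of raw proportions.
#' @return an `edd_candidates` object.
#' @export
candidates_from_distributions <- function(response_dist, predictor_dists,
                                          smooth_response = FALSE,
                                          smooth_predictors = TRUE) {
  if (is.null(names(predictor_dists))) {
    names(predictor_dists) <- vapply(predictor_dists, `[[`, "", "label")
  }
  take <- function(d, smooth) if (smooth) d$smoothed else d$proportions
  candidate_set(take(response_dist, smooth_response),
                lapply(predictor_dists, take, smooth = smooth_predictors),
                response_label = response_dist$label)
}

# OLS of y on the named predictor columns (with intercept); k for AICc counts
# coefficients plus the error variance.
ols_fit <- function(cs, terms) {
  y <- cs$response
  n <- cs$n
  X <- cbind(`(Intercept)` = 1, cs$predictors[, terms, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  k <- ncol(X) + 1L
  list(terms = terms,
       coefficients = fit$coefficients,
       rss = rss, tss = tss,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       aicc = aicc(max(rss, 1e-300), n, k),
       k = k, df_resid = n - ncol(X))
}

new_edd_fit <- function(cs, fit, type, extra = list()) {
  out <- c(list(response_label = cs$response_label,
                type = type,
                terms = fit$terms,
                coefficients = fit$coefficients,
                r_squared = fit$r_squared,
                rss = fit$rss,
                aicc = fit$aicc,
                n = cs$n, k = fit$k),
           extra)
  structure(out, class = "edd_fit")
}

#' @export
print.edd_fit <- function(x, ...) {
  cat("<edd_fit> ", x$response_label, " [", x$type, "]\n", sep = "")
  if (length(x$terms) == 0) {
    cat("  intercept-only model\n")
  } else {
    shares <- x$contributions
    lbl <- paste0(x$terms,
                  if (!is.null(shares)) sprintf(" (%.0f%%)", shares[x$terms]) else "",
                  collapse = " + ")
    cat("  terms: ", lbl, "\n", sep = "")
  }
  cat(sprintf("  R^2 = %.3f, AICc = %.2f, n = %d\n", x$r_squared, x$aicc, x$n))
  invisible(x)
}

#' Best single-process fit
#'
#' Ordinary least squares of the response on each candidate alone (with
#' intercept); the candidate with the lowest AICc (equivalently the highest
#' R-squared at fixed parameter count) is reported. A best-fit term is always
#' returned, even when it explains almost nothing, as for random uniform
#' responses.
#'
#' @param candidates an `edd_candidates` object.
#' @return an `edd_fit` with the selected term, its F-ratio and p-value, and
#'   a `ranking` data frame of all single-term fits.
#' @export
fit_single_best <- function(candidates) {
  cs <- candidates
  nm <- colnames(cs$predictors)
  if (length(nm) < 1L) stop("at least one predictor is required")
  if (sum((cs$response - mean(cs$response))^2) <= 0) {
    stop("constant response: total sum of squares is zero")
  }
  fits <- lapply(nm, function(p) ols_fit(cs, p))
  tab <- data.frame(term = nm,
                    r_squared = vapply(fits, `[[`, 0, "r_squared"),
                    aicc = vapply(fits, `[[`, 0, "aicc"),
                    stringsAsFactors = FALSE)
  ord <- order(tab$aicc, tab$term)
  best <- fits[[ord[1L]]]
  f_ratio <- (best$tss - best$rss) / (best$rss / best$df_resid)
  p_value <- stats::pf(f_ratio, 1, best$df_resid, lower.tail = FALSE)
  contrib <- stats::setNames(100, best$terms)
  new_edd_fit(cs, best, "single",
              extra = list(f_ratio = f_ratio, p_value = p_value,
                           contributions = contrib,
                           ranking = tab[ord, ]))
}

#' Sequential (entry-order) variance contribution of each model term
#'
#' Attributes to each term the incremental reduction in residual sum of
#' squares when it is added, in the given order, on top of the previous
#' terms, expressed as percent of the total model (explained) sum of squares.
#' Shares are non-negative and sum to 100.
#'
#' @param candidates an `edd_candidates` object.
#' @param terms character vector of predictor names in entry order.
#' @return named numeric vector of percents.
#' @export
contribution_decomposition <- function(candidates, terms) {
  cs <- candidates
  if (length(terms) < 1L) stop("at least one term is required")
  tss <- sum((cs$response - mean(cs$response))^2)
  rss_prev <- tss
  inc <- numeric(length(terms))
  for (j in seq_along(terms)) {
    f <- ols_fit(cs, terms[seq_len(j)])
    inc[j] <- rss_prev - f$rss
    rss_prev <- f$rss
  }
  model_ss <- tss - rss_prev
  if (model_ss <= 0) stop("zero model sum of squares: no variance explained")
  stats::setNames(100 * inc / model_ss, terms)
}

partial_f_p <- function(cs, base_fit, term) {
  f <- ols_fit(cs, c(base_fit$terms, term))
  dfr <- f$df_resid
  Fv <- (base_fit$rss - f$rss) / (f$rss / dfr)
  list(p = stats::pf(max(Fv, 0), 1, dfr, lower.tail = FALSE), fit = f)
}

#' Forward-stepwise process-mixture model under AICc
#'
#' Starting from the intercept-only model, the candidate whose partial-F
#' entry p-value is lowest is added at each step (ties broken alphabetically)
#' provided the addition lowers AICc; after each addition any included term
#' whose removal lowers AICc is dropped. Stepping stops when no addition or
#' removal lowers AICc. Finally, among the nested sub-models of the selected
#' terms, any model within delta-AICc < 2 of the best is considered
#' equivalent and the one with the fewest parameters is returned (parsimony
#' rule). Candidates nearly collinear (|r| > 0.999) with an already included
#' term are barred from entering, with a warning.
#'
#' @param candidates an `edd_candidates` object.
#' @param collinearity_r absolute correlation above which a later candidate
#'   is barred.
#' @return an `edd_fit` with selected terms (entry order), coefficients,
#'   R-squared, AICc, per-term `contributions` and a `trace` data frame of
#'   the stepping history. Negative term loadings are allowed but flagged via
#'   the `negative_terms` element.
#' @export
forward_stepwise <- function(candidates, collinearity_r = 0.999) {
  cs <- candidates
  nm <- colnames(cs$predictors)
  if (length(nm) < 1L) stop("at least one predictor is required")
  if (cs$n <= length(nm) + 2L) stop("too few positions for the candidate count")
  if (sum((cs$response - mean(cs$response))^2) <= 0) {
    stop("constant response: total sum of squares is zero")
  }

  current <- ols_fit(cs, character(0))
  entry_order <- character(0)
  barred <- character(0)
  trace <- list(list(step = 0L, action = "start", term = NA_character_,
                     aicc = current$aicc, delta = NA_real_))
  step <- 0L

  repeat {
    avail <- setdiff(nm, c(current$terms, barred))
    # bar near-collinear candidates
    if (length(current$terms) && length(avail)) {
      for (cand in avail) {
        r <- suppressWarnings(stats::cor(cs$predictors[, cand],
                                         cs$predictors[, current$terms, drop = FALSE]))
        if (any(abs(r) > collinearity_r, na.rm = TRUE)) {
          warning(sprintf("candidate '%s' barred: nearly collinear (|r| > %g) with an included term",
                          cand, collinearity_r))
          barred <- c(barred, cand)
        }
      }
      avail <- setdiff(avail, barred)
    }
    if (length(avail) == 0L) break

    entries <- lapply(avail, function(p) partial_f_p(cs, current, p))
    pvals <- vapply(entries, `[[`, 0, "p")
    ord <- order(pvals, avail)
    best_entry <- entries[[ord[1L]]]
    if (best_entry$fit$aicc >= current$aicc - 1e-9) break

    step <- step + 1L
    added <- avail[ord[1L]]
    entry_order <- c(entry_order, added)
    trace[[length(trace) + 1L]] <-
      list(step = step, action = "add", term = added,
           aicc = best_entry$fit$aicc, delta = best_entry$fit$aicc - current$aicc)
    current <- best_entry$fit

    # removal sweep
    while (length(current$terms) > 1L) {
      cand_fits <- lapply(current$terms, function(t)
        ols_fit(cs, setdiff(current$terms, t)))
      aiccs <- vapply(cand_fits, `[[`, 0, "aicc")
      j <- which.min(aiccs)
      if (aiccs[j] < current$aicc - 1e-9) {
        removed <- current$terms[j]
        step <- step + 1L
        trace[[length(trace) + 1L]] <-
          list(step = step, action = "remove", term = removed,
               aicc = aiccs[j], delta = aiccs[j] - current$aicc)
        entry_order <- setdiff(entry_order, removed)
        current <- cand_fits[[j]]
      } else break
    }
  }

  # parsimony: among nested sub-models of the selected terms, models within
  # delta-AICc < 2 of the best are equivalent; prefer fewer parameters
  terms <- entry_order
  if (length(terms) >= 1L) {
    subs <- unlist(lapply(0:length(terms), function(k)
      utils::combn(terms, k, simplify = FALSE)), recursive = FALSE)
    sub_fits <- lapply(subs, function(s) ols_fit(cs, terms[terms %in% s]))
    sub_aicc <- vapply(sub_fits, `[[`, 0, "aicc")
    ref <- min(sub_aicc)
    elig <- which(sub_aicc - ref < 2)
    sizes <- lengths(subs)[elig]
    pick <- elig[order(sizes, sub_aicc[elig])][1L]
    if (!setequal(subs[[pick]], terms)) {
      trace[[length(trace) + 1L]] <-
        list(step = step + 1L, action = "parsimony",
             term = paste(setdiff(terms, subs[[pick]]), collapse = ","),
             aicc = sub_aicc[pick], delta = sub_aicc[pick] - min(sub_aicc))
    }
    terms <- entry_order[entry_order %in% subs[[pick]]]
    current <- ols_fit(cs, terms)
  }

  contrib <- if (length(terms)) contribution_decomposition(cs, terms) else
    stats::setNames(numeric(0), character(0))
  neg <- names(current$coefficients)[-1][current$coefficients[-1] < 0]
  trace_df <- do.call(rbind, lapply(trace, function(r)
    data.frame(step = r$step, action = r$action, term = r$term,
               aicc = r$aicc, delta_aicc = r$delta, stringsAsFactors = FALSE)))
  new_edd_fit(cs, current, "stepwise",
              extra = list(contributions = contrib,
                           negative_terms = neg,
                           barred = barred,
                           trace = trace_df))
}
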