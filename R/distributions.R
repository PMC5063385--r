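#' Tricube local-linear (loess-style) smoothing of a positional series
#'
#' Smooths a 100-position (or general length-n) series by locally weighted
#' linear regression: at each position the `ceiling(alpha * n)` nearest
#' positions receive tricube weights and a degree-1 weighted least squares
#' fit is evaluated there. Constant and exactly linear series are reproduced
#' unchanged.
#'
#' @param series finite numeric vector.
#' @param alpha span: fraction of points in each local window, in (0, 1].
#'   The default 0.15 damps isolated extreme positions without erasing the
#'   platform-to-tip trend.
#' @return numeric vector of the same length.
#' @export
loess_smooth <- function(series, alpha = 0.15) {
  y <- as.numeric(series)
  n <- length(y)
  if (any(!is.finite(y))) stop("series must be finite")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]")
  }
  q <- ceiling(alpha * n)
  if (q < 3L) stop(sprintf("alpha = %g gives a %d-point neighborhood; at least 3 required", alpha, q))
  x <- seq_len(n)
  out <- numeric(n)
  for (i in x) {
    d <- abs(x - i)
    h <- sort.int(d, partial = q)[q]
    w <- numeric(n)
    in_w <- d < h | (d == h & h == 0)
    w[in_w] <- (1 - (d[in_w] / max(h, 1e-12))^3)^3
    w[d == h & h > 0] <- 0
    sw <- sum(w)
    xm <- sum(w * x) / sw
    ym <- sum(w * y) / sw
    sxx <- sum(w * (x - xm)^2)
    b <- if (sxx > 0) sum(w * (x - xm) * (y - ym)) / sxx else 0
    out[i] <- ym + b * (i - xm)
  }
  out
}

# Smooth a 400-position proportion series block-by-block so that no value
# borrows across the four edge boundaries.
smooth_blocks <- function(series, alpha = 0.15, block = 100L) {
  n <- length(series)
  if (n %% block != 0L) return(loess_smooth(series, alpha))
  out <- numeric(n)
  for (b in seq_len(n %/% block)) {
    i <- ((b - 1L) * block + 1L):(b * block)
    out[i] <- loess_smooth(series[i], alpha)
  }
  out
}

#' Assemble an assemblage distribution from damage counts
#'
#' @param counts non-negative integer vector (usually length 400).
#' @param label assemblage/experiment name.
#' @param n_tools number of tools behind the counts (NA when unknown, e.g.
#'   random draws).
#' @param alpha loess span used for the smoothed series.
#' @param smooth logical; compute the smoothed proportions?
#' @return an `edd_distribution`: list with `label`, `n_tools`, `counts`,
#'   `proportions` (counts normalized to sum 1), `smoothed` (per-edge-block
#'   loess of the proportions), `total_damage` and `alpha`.
#' @export
distribution_from_counts <- function(counts, label, n_tools = NA_integer_,
                                     alpha = 0.15, smooth = TRUE) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  props <- if (total > 0) counts / total else rep(NA_real_, length(counts))
  smoothed <- if (smooth && total > 0) smooth_blocks(props, alpha) else rep(NA_real_, length(counts))
  structure(list(label = as.character(label),
                 n_tools = n_tools,
                 counts = counts,
                 proportions = props,
                 smoothed = smoothed,
                 total_damage = total,
                 alpha = alpha,
                 empty = total == 0),
            class = "edd_distribution")
}

#' Aggregate per-tool damage vectors into an assemblage distribution
#'
#' Position counts are the number of tools with damage at each standardized
#' position; with `n` tools the total can be at most `n * 400` (every edge of
#' every tool completely damaged).
#'
#' @param vectors matrix of 0/1 damage vectors (tools in rows, 400 columns),
#'   or a list of such vectors.
#' @param label assemblage name.
#' @param alpha loess span for the smoothed series.
#' @param smooth logical; compute the smoothed series?
#' @return an `edd_distribution`; an empty collection yields `n_tools = 0`,
#'   all-zero counts and undefined (NA) proportions.
#' @export
aggregate_vectors <- function(vectors, label = "assemblage", alpha = 0.15,
                              smooth = TRUE) {
  if (is.list(vectors)) {
    vectors <- if (length(vectors)) do.call(rbind, vectors) else
      matrix(integer(0), ncol = 400L)
  }
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1L)
  if (nrow(vectors) == 0L) {
    d <- distribution_from_counts(integer(400L), label, n_tools = 0L,
                                  alpha = alpha, smooth = FALSE)
    return(d)
  }
  if (!all(vectors %in% c(0L, 1L))) stop("damage vectors must be binary")
  counts <- as.integer(colSums(vectors))
  distribution_from_counts(counts, label, n_tools = nrow(vectors),
                           alpha = alpha, smooth = smooth)
}

#' @export
print.edd_distribution <- function(x, ...) {
  cat("<edd_distribution> ", x$label, ": ",
      length(x$counts), " positions, n_tools = ", x$n_tools,
      ", total damage = ", x$total_damage, "\n", sep = "")
  invisible(x)
}

#' Expand a distribution into its multiset of damage positions
#'
#' @param dist an `edd_distribution`.
#' @param scale "tool" keeps whole-tool positions 1..400; "edge" collapses the
#'   four blocks onto shared 1..100 edge positions.
#' @return integer vector with one entry per damage occurrence.
#' @export
positions_from_distribution <- function(dist, scale = c("tool", "edge")) {
  scale <- match.arg(scale)
  pos <- rep.int(seq_along(dist$counts), dist$counts)
  if (scale == "edge") pos <- ((pos - 1L) %% 100L) + 1L
  pos
}

#' Damage totals per standardized edge block
#'
#' @param dist an `edd_distribution` over 400 positions.
#' @return named integer vector: dorsal_left, dorsal_right, ventral_left,
#'   ventral_right.
#' @export
edge_block_counts <- function(dist) {
  stopifnot(length(dist$counts) == 400L)
  c(dorsal_left = sum(dist$counts[1:100]),
    dorsal_right = sum(dist$counts[101:200]),
    ventral_left = sum(dist$counts[201:300]),
    ventral_right = sum(dist$counts[301:400]))
}

new_edd_test <- function(statistic_name, statistic, p_value, df = NA_integer_,
                         n_a = NA_integer_, n_b = NA_integer_) {
  structure(list(statistic_name = statistic_name,
                 statistic = unname(statistic),
                 df = df,
                 p_value = unname(min(max(p_value, 0), 1)),
                 n_a = n_a, n_b = n_b),
            class = "edd_test")
}

#' @export
print.edd_test <- function(x, ...) {
  cat("<edd_test> ", x$statistic_name, " = ", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(", df = ", x$df) else "",
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test on damage positions
#'
#' Compares two multisets of standardized damage positions via the supremum
#' of their empirical CDF difference, with the asymptotic two-sample p-value.
#' Ties (shared discrete positions) are handled by the standard ECDF
#' treatment.
#'
#' @param positions_a,positions_b non-empty integer vectors of damage
#'   positions (1..100 per-edge or 1..400 whole-tool).
#' @return an `edd_test` with `statistic_name = "KS_D"`.
#' @export
ks_two_sample <- function(positions_a, positions_b) {
  if (length(positions_a) == 0 || length(positions_b) == 0) {
    stop("both position multisets must be non-empty")
  }
  res <- suppressWarnings(stats::ks.test(positions_a, positions_b, exact = FALSE))
  new_edd_test("KS_D", res$statistic, res$p.value,
               n_a = length(positions_a), n_b = length(positions_b))
}

# upper tail of the Kolmogorov distribution, Q(t) = 2 sum (-1)^{k-1} e^{-2k^2t^2}
kolmogorov_q <- function(t) {
  if (t < 1e-3) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' One-sample Kolmogorov-Smirnov test against the discrete uniform
#'
#' Tests whether damage positions are uniformly distributed over their
#' standardized range. D is the supremum over the evaluation points
#' k = 1..m of |ECDF(k) - k/m|; the p-value is the asymptotic Kolmogorov
#' tail, which is slightly conservative on a discrete support.
#'
#' @param positions non-empty integer vector of damage positions.
#' @param n_positions size of the position range (default 100 if all
#'   positions are <= 100, else 400).
#' @return an `edd_test` with `statistic_name = "KS_D"`.
#' @export
ks_uniform <- function(positions, n_positions = NULL) {
  if (length(positions) == 0) stop("positions must be non-empty")
  if (is.null(n_positions)) n_positions <- if (max(positions) > 100L) 400L else 100L
  m <- as.integer(n_positions)
  if (any(positions < 1L | positions > m)) stop("positions outside 1..n_positions")
  n <- length(positions)
  Fn <- cumsum(tabulate(positions, nbins = m)) / n
  D <- max(abs(Fn - seq_len(m) / m))
  p <- kolmogorov_q(sqrt(n) * D)
  new_edd_test("KS_D", D, p, n_a = n, n_b = NA_integer_)
}

#' Chi-square balance test on two damage-occurrence counts
#'
#' Goodness-of-fit test of two observed counts (e.g. left vs right edge
#' totals) against equal expected counts, df = 1, without continuity
#' correction.
#'
#' @param count_a,count_b non-negative counts, not both zero.
#' @return an `edd_test` with `statistic_name = "chi_square"`.
#' @export
chi_square_balance <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0) stop("counts must be non-negative")
  if (count_a + count_b == 0) stop("at least one count must be positive")
  res <- suppressWarnings(stats::chisq.test(c(count_a, count_b), p = c(0.5, 0.5)))
  new_edd_test("chi_square", res$statistic, res$p.value, df = 1L,
               n_a = count_a, n_b = count_b)
}

#' Left/right and dorsal/ventral balance tests for a distribution
#'
#' @param dist an `edd_distribution` over 400 positions.
#' @return list of `edd_test`: `left_right` and `dorsal_ventral`.
#' @export
balance_tests <- function(dist) {
  b <- edge_block_counts(dist)
  list(left_right = chi_square_balance(b[["dorsal_left"]] + b[["ventral_left"]],
                                       b[["dorsal_right"]] + b[["ventral_right"]]),
       dorsal_ventral = chi_square_balance(b[["dorsal_left"]] + b[["dorsal_right"]],
                                           b[["ventral_left"]] + b[["ventral_right"]]))
}
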