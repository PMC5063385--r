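# deterministic synthetic regression scenarios over 100 "positions"
make_design <- function(n = 100) {
  x <- seq_len(n)
  list(p1 = sin(2 * pi * x / n), p2 = cos(2 * pi * x / n),
       p3 = (x - mean(x)) / n, p4 = exp(-(x - 20)^2 / 200))
}

# independent oracle: exhaustive subset search by AICc with the
# delta-AICc < 2 fewest-parameters rule
exhaustive_best <- function(cs) {
  nm <- colnames(cs$predictors)
  subs <- unlist(lapply(0:length(nm), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  fit1 <- function(terms) {
    X <- cbind(1, cs$predictors[, terms, drop = FALSE])
    rss <- sum(stats::lm.fit(X, cs$response)$residuals^2)
    aicc(max(rss, 1e-300), cs$n, ncol(X) + 1)
  }
  a <- vapply(subs, fit1, 0)
  elig <- which(a - min(a) < 2)
  pick <- elig[order(lengths(subs)[elig], a[elig])][1]
  sort(subs[[pick]])
}

test_that("aicc matches the closed-form and its algebraic identities", {
  set.seed(21)
  for (i in 1:20) {
    rss <- runif(1, 0.1, 50); n <- sample(20:500, 1); k <- sample(2:6, 1)
    expect_equal(aicc(rss, n, k),
                 n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                 tolerance = 1e-12)
    expect_equal(aicc(rss / 2, n, k), aicc(rss, n, k) - n * log(2),
                 tolerance = 1e-9)
    expect_gt(aicc(rss, 1000, k + 1) - aicc(rss, 1000, k), 2)
  }
  expect_error(aicc(-1, 100, 3), "positive")
  expect_error(aicc(1, 4, 3), "exceed")
})

test_that("single best fit identifies an affine transform exactly and matches brute force", {
  d <- make_design()
  y <- 2.5 - 1.2 * d$p2
  f <- fit_single_best(candidate_set(y, d))
  expect_identical(f$terms, "p2")
  expect_equal(f$r_squared, 1, tolerance = 1e-9)

  set.seed(22)
  for (i in 1:10) {
    y <- 0.7 * d$p1 + rnorm(100, sd = 0.5)
    cs <- candidate_set(y, d)
    f <- fit_single_best(cs)
    # brute force over all single-term OLS fits
    r2 <- vapply(names(d), function(p) {
      summary(stats::lm(y ~ cs$predictors[, p]))$r.squared
    }, 0)
    expect_identical(f$terms, names(which.max(r2)))
  }
  expect_error(fit_single_best(candidate_set(rep(1, 100), d)), "constant response")
})

test_that("a noise response still yields a (near-zero R-squared) best single fit", {
  set.seed(23)
  y <- rnorm(100)
  f <- fit_single_best(candidate_set(y, make_design()))
  expect_length(f$terms, 1)
  expect_lt(f$r_squared, 0.1)
})

test_that("stepwise recovers a known two-term mixture and ignores orthogonal noise", {
  set.seed(24)
  d <- make_design()
  y <- 0.6 * d$p1 + 0.4 * d$p4 + rnorm(100, sd = 0.02)
  f <- forward_stepwise(candidate_set(y, d))
  expect_setequal(f$terms, c("p1", "p4"))
  expect_gt(f$r_squared, 0.98)
  expect_true(all(f$contributions >= 0))
  expect_equal(sum(f$contributions), 100, tolerance = 1e-9)

  y0 <- rnorm(100, sd = 1)
  y0 <- stats::residuals(stats::lm(y0 ~ ., data = as.data.frame(d)))  # orthogonalized
  f0 <- forward_stepwise(candidate_set(y0, d))
  expect_length(f0$terms, 0)
  expect_equal(f0$r_squared, 0, tolerance = 1e-12)
})

test_that("stepwise agrees with exhaustive-subset AICc search on four predictors", {
  set.seed(25)
  d <- make_design()
  # identifiable signals well above the noise floor; on pure noise the greedy
  # path and the global search may legitimately disagree on chance flukes
  scenarios <- list(c(p1 = 0.8), c(p2 = 0.6, p4 = 0.5),
                    c(p1 = 0.7, p3 = 4, p4 = 0.6), c(p2 = 0.5, p3 = 2))
  for (sc in scenarios) {
    for (rep in 1:5) {
      y <- rnorm(100, sd = 0.05)
      for (nm in names(sc)) y <- y + sc[[nm]] * d[[nm]]
      cs <- candidate_set(y, d)
      f <- suppressWarnings(forward_stepwise(cs))
      expect_identical(sort(f$terms), exhaustive_best(cs))
    }
  }
})

test_that("stepwise selection is invariant to predictor input order", {
  set.seed(26)
  d <- make_design()
  y <- 0.5 * d$p2 + 0.3 * d$p3 + rnorm(100, sd = 0.05)
  f1 <- forward_stepwise(candidate_set(y, d))
  f2 <- forward_stepwise(candidate_set(y, rev(d)))
  expect_setequal(f1$terms, f2$terms)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("nearly collinear candidates are barred with a warning", {
  set.seed(27)
  d <- make_design()
  d$p1_copy <- d$p1 + rnorm(100, sd = 1e-6)
  y <- 0.8 * d$p1 + rnorm(100, sd = 0.05)
  expect_warning(f <- forward_stepwise(candidate_set(y, d)), "collinear")
  expect_false(all(c("p1", "p1_copy") %in% f$terms))
})

test_that("R-squared is non-decreasing under nested term addition", {
  set.seed(28)
  d <- make_design()
  y <- 0.4 * d$p1 + 0.2 * d$p2 + rnorm(100, sd = 0.3)
  cs <- candidate_set(y, d)
  nm <- names(d)
  r2 <- vapply(seq_along(nm), function(k)
    lithicedd:::ols_fit(cs, nm[seq_len(k)])$r_squared, 0)
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("contribution decomposition is exact for orthogonal predictors", {
  n <- 100
  x <- seq_len(n)
  # orthogonal design: centered sine and cosine harmonics
  d <- list(a = sin(2 * pi * x / n), b = cos(4 * pi * x / n))
  expect_lt(abs(stats::cor(d$a, d$b)), 1e-10)
  y <- 1.5 * d$a + 0.5 * d$b
  cs <- candidate_set(y, d)
  shares <- contribution_decomposition(cs, c("a", "b"))
  r2a <- summary(stats::lm(y ~ d$a))$r.squared
  r2b <- summary(stats::lm(y ~ d$b))$r.squared
  expect_equal(unname(shares["a"] / shares["b"]), r2a / r2b, tolerance = 1e-6)
  expect_equal(sum(shares), 100, tolerance = 1e-9)

  single <- contribution_decomposition(cs, "a")
  expect_equal(unname(single), 100)
  expect_error(contribution_decomposition(candidate_set(rnorm(100), d), character(0)),
               "at least one term")
})
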