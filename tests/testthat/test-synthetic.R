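test_that("profile construction validates weights and edge multipliers", {
  expect_error(process_profile("bad", uniform_weight = 0.8), "sum to 1")
  expect_error(process_profile("bad", uniform_weight = -1), "non-negative")
  expect_error(process_profile("bad", edge_weights = c(dorsal_left = 1)), "four edges")
  p <- process_profile("ok")
  x <- seq(0.05, 99.95, by = 0.1)
  expect_equal(sum(profile_density(p, x)) * 0.1, 1, tolerance = 1e-6)
})

test_that("fixed seeds reproduce generator output exactly", {
  p <- default_process_profiles()$armature_quartzite
  a <- sample_process_distribution(p, n_tools = 30, seed = 99)
  b <- sample_process_distribution(p, n_tools = 30, seed = 99)
  expect_identical(a$vectors, b$vectors)
  expect_identical(random_uniform_distribution(500, seed = 5)$counts,
                   random_uniform_distribution(500, seed = 5)$counts)
  spec <- mixture_spec(c(trampling = 0.5, tumbling = 0.5), 40, seed = 3)
  expect_identical(generate_mixture(spec)$vectors, generate_mixture(spec)$vectors)
})

test_that("random uniform draws conserve totals at the reference sizes", {
  for (n in c(10000, 1000, 500, 100, 50)) {
    d <- random_uniform_distribution(n, seed = n)
    expect_identical(d$total_damage, as.integer(n))
    expect_true(is.na(d$n_tools))
  }
  expect_error(random_uniform_distribution(0), "at least 1")
})

test_that("armature damage is tip-weighted and uniform profiles pass uniformity", {
  set.seed(31)
  arm <- sample_process_distribution(default_process_profiles()$armature_quartzite,
                                     n_tools = 400)$distribution
  for (block in 0:3) {
    pos <- positions_from_distribution(arm)
    pos <- pos[pos > block * 100 & pos <= (block + 1) * 100] - block * 100
    expect_gt(mean(pos), 60)
  }
  flat <- process_profile("flat", uniform_weight = 1, scars_per_tool = 6)
  d <- sample_process_distribution(flat, n_tools = 300, seed = 32)$distribution
  expect_gt(ks_uniform(positions_from_distribution(d))$p_value, 0.05)
})

test_that("butchery asymmetry is chi-square significant at 20 tools", {
  d <- sample_process_distribution(default_process_profiles()$field_dressing,
                                   n_tools = 20, seed = 33)$distribution
  expect_lt(balance_tests(d)$left_right$p_value, 0.05)
})

test_that("per-edge damage scales near-linearly with the scar-rate parameter", {
  base <- process_profile("lin1", uniform_weight = 1, scars_per_tool = 1)
  dbl <- process_profile("lin2", uniform_weight = 1, scars_per_tool = 2)
  t1 <- sample_process_distribution(base, n_tools = 200, seed = 34)$distribution$total_damage
  t2 <- sample_process_distribution(dbl, n_tools = 200, seed = 35)$distribution$total_damage
  expect_lt(abs(t2 / t1 - 2), 0.2)
})

test_that("expected profile curves match large-sample empirical aggregates", {
  p <- default_process_profiles()$tumbling
  exp_d <- profile_expected_distribution(p)
  expect_equal(sum(exp_d$proportions), 1, tolerance = 1e-9)
  set.seed(36)
  emp <- sample_process_distribution(p, n_tools = 4000)$distribution
  expect_gt(stats::cor(exp_d$proportions, emp$proportions), 0.97)
})

test_that("mixtures record ground truth and degenerate mixtures match their process", {
  profs <- default_process_profiles()
  spec <- mixture_spec(c(armature_quartzite = 0.7, trampling = 0.3), 60,
                       seed = 37, label = "mix")
  mix <- generate_mixture(spec, profs)
  expect_identical(mix$true_weights, spec$weights)
  expect_identical(length(mix$assignments), 60L)
  expect_true(all(mix$assignments %in% names(spec$weights)))
  expect_identical(mix$distribution$n_tools, 60L)

  # a weight-1 "mixture" is the same generator as a direct process sample;
  # compare at the curve level (occurrence-level KS over-rejects because the
  # ~3 positions of one scar are not independent draws)
  pure <- generate_mixture(mixture_spec(c(tumbling = 1), 400, seed = 38), profs)
  direct <- sample_process_distribution(profs$tumbling, n_tools = 400, seed = 39)
  model_curve <- profile_expected_distribution(profs$tumbling)$smoothed
  expect_gt(stats::cor(pure$distribution$smoothed, model_curve), 0.7)
  expect_gt(stats::cor(direct$distribution$smoothed, model_curve), 0.7)
  shares_a <- edge_block_counts(pure$distribution) / pure$distribution$total_damage
  shares_b <- edge_block_counts(direct$distribution) / direct$distribution$total_damage
  expect_lt(max(abs(shares_a - shares_b)), 0.05)
  expect_error(generate_mixture(mixture_spec(c(nonexistent = 1), 10)), "unknown process")
  expect_error(mixture_spec(c(a = 0.5, b = 0.4), 10), "sum to 1")
})

test_that("synthetic tools satisfy the geometry invariants end to end", {
  tool <- generate_synthetic_tool(length = 60, base_width = 30)
  e <- split_edges(tool$faces$dorsal$outline, tool$faces$dorsal$platform_anchor)
  expect_lt(abs(e$left$total_length - e$right$total_length),
            0.01 * e$left$total_length)
  expect_error(generate_synthetic_tool(length = -1), "positive")

  # full-perimeter damage on a batch reaches the stated capacity
  full_scars <- expand.grid(face = c("dorsal", "ventral"),
                            side = c("left", "right"),
                            stringsAsFactors = FALSE)
  full_scars$center <- 50; full_scars$length <- 100
  vecs <- t(vapply(1:100, function(i)
    as.integer(build_damage_vector(generate_synthetic_tool(scars = full_scars,
                                                           tool_id = paste0("t", i)))),
    integer(400)))
  d <- aggregate_vectors(vecs, "capacity")
  expect_identical(d$total_damage, 40000L)
})
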