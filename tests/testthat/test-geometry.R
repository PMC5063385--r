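test_that("split_edges recovers symmetric arcs on an isoceles triangle", {
  tri <- isoceles_triangle(half_base = 1, height = 3)
  e <- split_edges(tri, c(0, 0))
  expect_equal(e$left$total_length, e$right$total_length, tolerance = 1e-12)
  # tip is the apex
  expect_equal(unname(e$left$vertices[nrow(e$left$vertices), ]), c(0, 3))
  expect_equal(unname(e$right$vertices[nrow(e$right$vertices), ]), c(0, 3))
})

test_that("split_edges on a square from one corner reaches the opposite corner", {
  e <- split_edges(unit_square(2), c(0, 0))
  expect_equal(unname(e$left$vertices[nrow(e$left$vertices), ]), c(2, 2))
  expect_equal(e$left$total_length, 4)
  expect_equal(e$right$total_length, 4)
})

test_that("tip equals the brute-force farthest vertex and arcs partition the perimeter", {
  set.seed(101)
  for (i in 1:25) {
    ring <- random_star_polygon(n = sample(6:16, 1))
    anchor <- ring[1, ]
    e <- split_edges(ring, anchor)
    # independent oracle: exhaustive vertex scan
    d <- sqrt(rowSums(sweep(ring, 2, anchor)^2))
    expect_equal(max(sqrt(sum((e$left$vertices[nrow(e$left$vertices), ] - anchor)^2))),
                 max(d), tolerance = 1e-9)
    perim <- sum(sqrt(rowSums(diff(rbind(ring, ring[1, ]))^2)))
    expect_equal(e$left$total_length + e$right$total_length, perim,
                 tolerance = 1e-9 * perim)
  }
})

test_that("split_edges rejects degenerate input and distant anchors", {
  expect_error(split_edges(rbind(c(0, 0), c(1, 0)), c(0, 0)), "3 vertices")
  collinear <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_error(split_edges(collinear, c(0, 0)), "zero area")
  expect_error(split_edges(unit_square(2), c(5, 5)), "platform anchor")
  bowtie <- rbind(c(0, 0), c(2, 1), c(2, 0), c(0, 2))
  expect_error(split_edges(bowtie, c(0, 0)), "self-intersecting")
})

test_that("tied tip candidates produce a deterministic choice with a warning", {
  # anchor at the base midpoint of a square: both far corners are equidistant
  expect_warning(e <- split_edges(unit_square(2), c(1, 0)), "ambiguous tip")
  e2 <- suppressWarnings(split_edges(unit_square(2), c(1, 0)))
  expect_identical(e$left$vertices, e2$left$vertices)
})

test_that("span_to_positions reproduces the 3%-scar worked example", {
  expect_identical(span_to_positions(48.5, 51.5), 49:51)
  expect_identical(span_to_positions(0, 100), 1:100)
  expect_identical(span_to_positions(30, 30), integer(0))
  expect_identical(span_to_positions(0, 1.6), 1:2)
})

test_that("project_damage maps a centered 3% scar to positions 49-51 and misses disjoint scars", {
  tool <- generate_synthetic_tool()
  e <- split_edges(tool$faces$dorsal$outline, tool$faces$dorsal$platform_anchor)
  scar <- straddle_scar(e$left, 48.5, 51.5)
  expect_identical(project_damage(scar, e$left), 49:51)
  far <- scar
  far[, 1] <- far[, 1] + 500
  expect_identical(project_damage(far, e$left), integer(0))
})

test_that("damage vectors are invariant to uniform scaling and rigid motion", {
  tool <- generate_synthetic_tool(scars = data.frame(
    face = c("dorsal", "ventral"), side = c("left", "right"),
    center = c(50, 20), length = c(3, 6)))
  v0 <- build_damage_vector(tool)
  transform_tool <- function(tool, f) {
    for (fn in c("dorsal", "ventral")) {
      face <- tool$faces[[fn]]
      face$outline <- f(face$outline)
      face$platform_anchor <- drop(f(rbind(face$platform_anchor)))
      face$scars <- lapply(face$scars, function(s) { s$ring <- f(s$ring); s })
      tool$faces[[fn]] <- face
    }
    tool
  }
  v_scaled <- build_damage_vector(transform_tool(tool, function(m) m * 7.3))
  expect_identical(v_scaled, v0)
  v_rigid <- build_damage_vector(transform_tool(tool, function(m)
    rotate_translate(m, angle = 0.83, shift = c(-40, 12.5))))
  expect_identical(v_rigid, v0)
})

test_that("interval marking agrees with a dense point-containment oracle", {
  skip_if_not_installed("mgcv")
  set.seed(202)
  for (rep in 1:5) {
    center <- stats::runif(1, 15, 85)
    len <- stats::runif(1, 2, 12)
    tool <- generate_synthetic_tool(
      asymmetry = stats::runif(1, -0.2, 0.2),
      scars = data.frame(face = "dorsal", side = "left",
                         center = center, length = len))
    face <- tool$faces$dorsal
    e <- split_edges(face$outline, face$platform_anchor)$left
    got <- project_damage(face$scars[[1]]$ring, e)
    # oracle: 1000 evenly spaced points, containment via mgcv::in.out
    s <- seq(0, e$total_length, length.out = 1000)
    pts <- t(vapply(s, function(si)
      lithicedd:::point_at_arc(e$vertices, e$cum_lengths, si), numeric(2)))
    ring <- face$scars[[1]]$ring
    inside <- mgcv::in.out(rbind(ring, ring[1, ]), pts)
    pct <- s / e$total_length * 100
    oracle <- sort(unique(pmin(pmax(round(pct[inside]), 1), 100)))
    differs <- union(setdiff(got, oracle), setdiff(oracle, got))
    # disagreement only at span boundaries (sampling resolution 0.1%)
    expect_lte(length(differs), 2)
    expect_true(all(differs %in% c(min(got) - 1, min(got), max(got), max(got) + 1)))
  }
})

test_that("build_damage_vector writes blocks in the standard layout", {
  expect_identical(sum(build_damage_vector(generate_synthetic_tool())), 0L)
  v <- build_damage_vector(mid_scar_tool(face = "dorsal", side = "left"))
  expect_identical(which(v == 1L), 49:51)
  v <- build_damage_vector(mid_scar_tool(face = "dorsal", side = "right"))
  expect_identical(which(v == 1L), 149:151)
  v <- build_damage_vector(mid_scar_tool(face = "ventral", side = "left"))
  expect_identical(which(v == 1L), 249:251)
  v <- build_damage_vector(mid_scar_tool(face = "ventral", side = "right"))
  expect_identical(which(v == 1L), 349:351)
})

test_that("a tool with a missing face is rejected with its id", {
  tool <- generate_synthetic_tool(tool_id = "broken-007")
  tool$faces$ventral <- NULL
  expect_error(build_damage_vector(tool), "broken-007")
})

test_that("vector totals match an independent per-scar interval count", {
  set.seed(303)
  for (rep in 1:5) {
    sc <- data.frame(face = sample(c("dorsal", "ventral"), 3, TRUE),
                     side = sample(c("left", "right"), 3, TRUE),
                     center = stats::runif(3, 10, 90),
                     length = stats::runif(3, 1, 8))
    tool <- generate_synthetic_tool(scars = sc)
    v <- build_damage_vector(tool)
    # oracle: union of analytic spans per block
    marks <- integer(0)
    for (i in seq_len(nrow(sc))) {
      off <- (sc$face[i] == "ventral") * 200L + (sc$side[i] == "right") * 100L
      pos <- span_to_positions(sc$center[i] - sc$length[i] / 2,
                               sc$center[i] + sc$length[i] / 2)
      marks <- union(marks, off + pos)
    }
    expect_setequal(which(v == 1L), marks)
  }
})
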