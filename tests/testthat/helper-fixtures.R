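# Shared fixture builders. Everything is generated in code; no data files.

unit_square <- function(side = 2) {
  rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
}

isoceles_triangle <- function(half_base = 1, height = 3) {
  rbind(c(-half_base, 0), c(half_base, 0), c(0, height))
}

# star-shaped simple polygon with random radii around the origin
random_star_polygon <- function(n = 12, r_min = 1, r_max = 2) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, r_max)
  cbind(r * cos(theta), r * sin(theta))
}

# rectangle straddling the polyline of `edge` between percent positions a..b
straddle_scar <- function(edge, a, b, depth = 0.5) {
  s <- seq(a / 100 * edge$total_length, b / 100 * edge$total_length, length.out = 8)
  pts <- t(vapply(s, function(si)
    lithicedd:::point_at_arc(edge$vertices, edge$cum_lengths, si), numeric(2)))
  nrm <- t(vapply(s, function(si)
    lithicedd:::normal_at_arc(edge$vertices, edge$cum_lengths, si), numeric(2)))
  rbind(pts + depth * nrm, (pts - depth * nrm)[rev(seq_len(nrow(pts))), ])
}

rotate_translate <- function(m, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(m %*% t(R), 2, -shift)
}

mid_scar_tool <- function(center = 50, len = 3, face = "dorsal", side = "left") {
  generate_synthetic_tool(scars = data.frame(face = face, side = side,
                                             center = center, length = len))
}
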