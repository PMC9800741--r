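# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Arc length positions (um) along a polyline (n x 3 matrix).
polyline_arc <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# Linear interpolation of a point at arc position s along a polyline.
polyline_point_at <- function(pts, s) {
  arc <- polyline_arc(pts)
  s <- min(max(s, 0), max(arc))
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  t <- if (arc[i + 1] > arc[i]) (s - arc[i]) / (arc[i + 1] - arc[i]) else 0
  pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
}

# Unit tangent at arc position s, estimated from neighboring samples.
polyline_tangent_at <- function(pts, s, window_um = 4) {
  arc <- polyline_arc(pts)
  p0 <- polyline_point_at(pts, s - window_um / 2)
  p1 <- polyline_point_at(pts, s + window_um / 2)
  d <- p1 - p0
  n <- sqrt(sum(d^2))
  if (n < 1e-9) {
    i <- min(max(findInterval(s, arc), 1L), nrow(pts) - 1L)
    d <- pts[i + 1, ] - pts[i, ]
    n <- sqrt(sum(d^2))
  }
  d / n
}
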