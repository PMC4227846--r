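# Independent oracles used by several test files.

# dense grid search over (a, b, c) for the gompertz least-squares problem;
# distances in meters. Returns the best RSS found on the grid.
grid_search_rss <- function(d_m, y, n_grid = 50,
                            a_range = c(0.05, 1.2),
                            b_range = c(0.01, 2.5),
                            c_range = c(1e-5, 1e-3)) {
  a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
  b_grid <- seq(b_range[1], b_range[2], length.out = n_grid)
  c_grid <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n_grid))
  sy2 <- sum(y^2)
  best <- Inf
  for (cc in c_grid) {
    E <- exp(-cc * d_m)
    for (b in b_grid) {
      g <- exp(-b * E)
      s1 <- sum(y * g)
      s2 <- sum(g * g)
      rss <- sy2 - 2 * a_grid * s1 + a_grid^2 * s2
      m <- min(rss)
      if (m < best) best <- m
    }
  }
  best
}
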