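# Independent oracles used across the suite.

# brute-force toroidal distance: minimum Euclidean distance over the nine
# periodic images of b
nine_image_distance <- function(a, b, side) {
  shifts <- expand.grid(dx = c(-side, 0, side), dy = c(-side, 0, side))
  min(sqrt((a[1] - (b[1] + shifts$dx))^2 + (a[2] - (b[2] + shifts$dy))^2))
}

# all-pairs neighbourhood filter built on the image oracle
brute_neighbors <- function(points, center, radius, side) {
  d <- vapply(seq_len(nrow(points)), function(i)
    nine_image_distance(center, points[i, ], side), numeric(1))
  which(d <= radius)
}

# classic (tie-free) Kendall's W
classic_w <- function(tab) {
  m <- nrow(tab); n <- ncol(tab)
  ranks <- t(apply(tab, 1, rank))
  R <- colSums(ranks)
  12 * sum((R - mean(R))^2) / (m^2 * (n^3 - n))
}

# a small world that runs in milliseconds
small_cfg <- function(...) {
  args <- list(arena_side = 100, n_steps = 60, n_food_init = 200,
               n_display_init = 200)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
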