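# shared fixtures and independent reference implementations

# reference colocalization ratios for proteins of known oligomeric state
# (cold-methanol values: monomer, two dimers, trimer, tetramer)
reference_ratios <- function() {
  tibble::tibble(
    protein = c("barttin", "ClC-2", "bClC-K", "EAAT2", "Kir2.1"),
    n = c(1, 2, 2, 3, 4),
    pd = c(0.172, 0.237, 0.241, 0.293, 0.411))
}

# brute-force O(n^2) DBSCAN with the same deterministic semantics as the
# package implementation: core = >= min_pts within eps (self included);
# clusters = components of cores, numbered by lexicographic rank of the
# first core; border points join the lowest-ranked core neighbour
ref_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (!n) return(integer())
  D <- as.matrix(stats::dist(cbind(x, y))) <= eps
  core <- rowSums(D) >= min_pts
  rank <- order(order(x, y))
  labels <- integer(n)
  cl <- 0L
  for (i in order(x, y)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      nb <- which(D[q, ] & core & labels == 0L)
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    nb <- which(D[i, ] & core)
    if (length(nb)) labels[i] <- labels[nb[which.min(rank[nb])]]
  }
  labels
}

# Monte-Carlo oracle for the double-loss detection model: simulate subunit
# states directly and condition on marker-side visibility (>= 1 survivor)
mc_pd_modified <- function(n, p, m, draws = 1e6) {
  k <- rbinom(draws, n, 1 - m)
  k <- k[k > 0]
  visible <- rbinom(length(k), k, p) > 0
  list(est = mean(visible), se = sqrt(mean(visible) * (1 - mean(visible)) / length(k)))
}

# small registered (no drift / no aberration) dual-color scene
quick_scene <- function(seed, oligomer = 2, p = 0.17, m = 0.30,
                        background_red = 0.8, field = 12000, frames = 200,
                        density = 1.5, ...) {
  cfg <- scene_config(field = field,
                      cell = c(500, 0.7 * field, 500, field - 500),
                      background = c(0.75 * field, field - 500, 500, field - 500),
                      complex_density = density, oligomer = oligomer,
                      p = p, m = m,
                      background_density = c(green = 0, red = background_red),
                      frames = frames, drift_sigma = 0, drift_linear = c(0, 0),
                      lca = list(K = 0, x0 = 0, y0 = 0), n_beads = 0,
                      seed = seed, ...)
  simulate_scene(cfg)
}
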