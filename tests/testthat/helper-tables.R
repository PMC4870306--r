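# Shared fixtures built in code: expected counts of discretized (bivariate)
# normal tables, and small simulated datasets.

# m1 x m2 table of expected counts for a discretized bivariate normal
bvn_table <- function(t1, t2, rho, N) {
  ordshift:::bvn_cell_probs(t1, t2, rho) * N
}

# multinomial draw arranged as a table
bvn_table_sampled <- function(t1, t2, rho, N) {
  p <- ordshift:::bvn_cell_probs(t1, t2, rho)
  matrix(rmultinom(1, N, as.vector(p)), nrow(p), ncol(p))
}

# grid-search oracle: maximize the multinomial log-likelihood over rho with
# the standardized thresholds held fixed
grid_rho_oracle <- function(tab, t1, t2, step = 1e-3) {
  grid <- seq(-0.999, 0.999, by = step)
  ll <- vapply(grid, function(r) {
    P <- ordshift:::bvn_cell_probs(t1, t2, r)
    sum(tab[tab > 0] * log(P[tab > 0]))
  }, numeric(1))
  grid[which.max(ll)]
}

random_small_table <- function(m1, m2, N = 400) {
  t1 <- sort(rnorm(m1 - 1))
  t2 <- sort(rnorm(m2 - 1))
  rho <- runif(1, -0.85, 0.85)
  list(tab = bvn_table_sampled(t1, t2, rho, N), t1 = t1, t2 = t2, rho = rho)
}

# deterministic small dataset for interface tests
tiny_dataset <- function(n = 40, seed = 99) {
  cfg <- sim_config(n_subjects = n, n_items = 2, m = 4,
                    thresholds = c(-1, 0, 1), seed = seed)
  simulate_ordinal(cfg)
}

tiny_config <- function() {
  scale_config(tibble::tibble(item = c("item_1", "item_2"), scale = "toy", m = 4))
}
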