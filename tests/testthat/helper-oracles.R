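# Hand-rolled oracles, independent of the package's vectorized/compiled paths.

# interaction profile by explicit double loop over family pairs
oracle_profile <- function(families, params) {
  n <- nrow(families)
  tau2 <- params$tau^2
  friend <- rival <- numeric(n)
  for (i in seq_len(n)) {
    fsum <- rsum <- 0
    for (j in seq_len(n)) {
      dtt <- (families$t1[i] - families$t1[j])^2 +
        (families$t2[i] - families$t2[j])^2
      dtp <- (families$t1[i] - families$p1[j])^2 +
        (families$t2[i] - families$p2[j])^2
      dpt <- (families$p1[i] - families$t1[j])^2 +
        (families$p2[i] - families$t2[j])^2
      dpp <- (families$p1[i] - families$p1[j])^2 +
        (families$p2[i] - families$p2[j])^2
      fsum <- fsum + exp(-min(dtt, dtp, dpt) / tau2)
      rsum <- rsum + exp(-dpp / tau2)
    }
    friend[i] <- fsum / n
    rival[i] <- rsum / n
  }
  r <- params$b * exp(-params$d_c * (1 - friend) - params$d_m * rival)
  list(friend = friend, rival = rival, r = r)
}

# cycle structure of a functional graph by naive path-following from a node
oracle_cycle_from <- function(edge_map, start) {
  seen <- integer(0)
  v <- start
  while (!(v %in% seen)) {
    seen <- c(seen, v)
    v <- edge_map[v]
  }
  sum(seq_along(seen) >= match(v, seen))  # nodes from first visit of v
}

# all functional graphs on k nodes, enumerated as base-k integers
all_functional_graphs <- function(k) {
  grids <- rep(list(seq_len(k)), k)
  as.matrix(do.call(expand.grid, grids))
}

# random families tibble
rand_families <- function(n, scale = 3) {
  tibble::tibble(t1 = runif(n, -scale, scale), t2 = runif(n, -scale, scale),
                 p1 = runif(n, -scale, scale), p2 = runif(n, -scale, scale))
}
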