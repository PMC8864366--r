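test_that("BIC clustering recovers well-separated clans and resists noise blobs", {
  fx <- make_clan_cloud(kind = "generalized", k = 3, separation = 10,
                        noise_sd = 0.1, seed = 3)
  cp <- cluster_families(fx$points, seed = 1)
  expect_equal(cp$k, 3L)
  # labels match ground truth up to permutation
  cross <- table(cp$labels, fx$points$clan)
  expect_true(all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1))

  # one tight blob stays one cluster
  withr::with_seed(4, blob <- matrix(rnorm(120 * 4, sd = 0.01), ncol = 4))
  expect_equal(cluster_families(blob, seed = 1)$k, 1L)

  # a single point is its own trivial partition
  one <- cluster_families(matrix(c(1, 2, 3, 4), 1), seed = 1)
  expect_equal(one$k, 1L)
  expect_equal(one$labels, 1L)

  expect_error(cluster_families(matrix(numeric(0), 0, 4)), "extinct")
})

test_that("marriage and descent edges follow the centroid geometry", {
  # two clans preferring each other
  dual <- make_clan_cloud(kind = "dual", noise_sd = 0, seed = 1)
  part <- list(labels = dual$points$clan, centroids = dual$centroids, k = 2L,
               sizes = c(30L, 30L))
  g <- build_clan_graphs(part)
  expect_equal(g$marriage, c(2L, 1L))
  # matrilineal: the maternal line self-loops, the paternal line alternates
  expect_equal(g$descent_maternal, c(1L, 2L))
  expect_equal(g$descent_paternal, c(2L, 1L))

  # one self-preferring clan: all self-loops
  endo <- make_clan_cloud(kind = "endogamy", noise_sd = 0, seed = 1)
  pe <- list(labels = endo$points$clan, centroids = endo$centroids, k = 1L,
             sizes = 30L)
  ge <- build_clan_graphs(pe)
  expect_equal(ge$marriage, 1L)
  expect_equal(ge$descent_paternal, 1L)

  # three clans preferring each other cyclically
  gen <- make_clan_cloud(kind = "generalized", k = 3, noise_sd = 0, seed = 1)
  pg <- list(labels = gen$points$clan, centroids = gen$centroids, k = 3L,
             sizes = rep(30L, 3))
  gg <- build_clan_graphs(pg)
  expect_equal(gg$marriage, c(2L, 3L, 1L))
  expect_equal(gg$descent_paternal, c(1L, 2L, 3L))  # patrilineal self-loops
})

test_that("cycle lengths agree with brute-force path-following on small graphs", {
  expect_equal(cycle_length(1L)$length, 1L)
  expect_equal(cycle_length(c(2L, 1L))$length, 2L)
  expect_equal(cycle_length(c(2L, 3L, 1L))$length, 3L)
  # exhaustive check against the naive oracle for all graphs on <= 5 nodes
  for (k in 1:5) {
    graphs <- all_functional_graphs(k)
    for (gi in seq_len(nrow(graphs))) {
      g <- as.integer(graphs[gi, ])
      got <- cycle_length(g)
      oracle_lens <- unique(vapply(1:k, function(v) oracle_cycle_from(g, v), 0L))
      expect_true(got$length %in% oracle_lens)
      expect_identical(got$inconsistent, length(oracle_lens) > 1L)
    }
  }
  # the dominant cycle is the one holding the most families
  g <- c(1L, 3L, 2L)  # self-loop {1} and 2-cycle {2, 3}
  expect_equal(cycle_length(g, weights = c(10, 1, 1))$length, 1L)
  expect_equal(cycle_length(g, weights = c(1, 10, 10))$length, 2L)
  expect_true(cycle_length(g)$inconsistent)
  # two cycles of the same length are not inconsistent (restricted exchange)
  g2 <- c(2L, 1L, 4L, 3L)
  expect_equal(cycle_length(g2)$length, 2L)
  expect_false(cycle_length(g2)$inconsistent)
})

test_that("descent classification reads the centroid spread per trait axis", {
  mkpart <- function(tmat) {
    k <- nrow(tmat)
    list(labels = seq_len(k),
         centroids = cbind(t1 = tmat[, 1], t2 = tmat[, 2],
                           p1 = rep(0, k), p2 = rep(0, k)),
         k = k, sizes = rep(1L, k))
  }
  expect_equal(classify_descent(mkpart(rbind(c(0, 0), c(5, 0)))), "patrilineal")
  expect_equal(classify_descent(mkpart(rbind(c(0, 0), c(0, 5)))), "matrilineal")
  square <- rbind(c(0, 0), c(0, 5), c(5, 0), c(5, 5))
  expect_equal(classify_descent(mkpart(square)), "double")
  expect_equal(classify_descent(mkpart(rbind(c(0, 0)))), "undivided")
  expect_equal(classify_descent(mkpart(rbind(c(0, 0), c(0.1, 0.1)))),
               "ambiguous")
  # the threshold is theta * tau
  expect_equal(classify_descent(mkpart(rbind(c(0, 0), c(3, 0))), tau = 1,
                                theta = 4), "ambiguous")
})

test_that("full classification recovers every fixture geometry", {
  cases <- list(
    list(kind = "endogamy", axis = "t1", structure = "clan_endogamy",
         descent = "undivided"),
    list(kind = "dual", axis = "t2", structure = "dual_organization",
         descent = "matrilineal"),
    list(kind = "dual", axis = "t1", structure = "dual_organization",
         descent = "patrilineal"),
    list(kind = "generalized", axis = "t1", structure = "generalized_exchange",
         descent = "patrilineal"),
    list(kind = "restricted", axis = "both", structure = "restricted_exchange",
         descent = "double")
  )
  for (cs in cases) {
    fx <- make_clan_cloud(kind = cs$kind, descent_axis = cs$axis, seed = 7)
    cls <- classify_kinship(fx$points, seed = 1)
    expect_equal(cls$structure, cs$structure)
    expect_equal(cls$descent_system, cs$descent)
    expect_equal(cls$C_m, fx$truth$C_m)
    expect_equal(cls$C_d, fx$truth$C_d)
  }
  # translation invariance: shifting every family leaves the verdict unchanged
  fx <- make_clan_cloud(kind = "restricted", seed = 8)
  shifted <- dplyr::mutate(fx$points, t1 = t1 + 13, t2 = t2 - 7,
                           p1 = p1 + 13, p2 = p2 - 7)
  a <- glance(classify_kinship(fx$points, seed = 2))
  b <- glance(classify_kinship(shifted, seed = 2))
  expect_equal(a, b)
  # an empty cloud is reported extinct
  expect_equal(classify_kinship(fx$points[0, ])$structure, "extinct")
})

test_that("event tracing reproduces the centroid graphs on clean flows", {
  fx <- make_clan_cloud(kind = "dual", noise_sd = 0.05, seed = 9)
  part <- cluster_families(fx$points, seed = 1)
  # build a synthetic event log consistent with the geometry: brides of each
  # clan marry grooms of the other, children carry (t1 groom, t2 bride)
  ct <- part$centroids
  mk_ev <- function(b, g, n) {
    tibble::tibble(
      step = 1L, society_id = 1L, groom_family_id = 1L, bride_family_id = 2L,
      child_family_id = 3L,
      g_t1 = ct[g, "t1"], g_t2 = ct[g, "t2"], g_p1 = ct[g, "p1"],
      g_p2 = ct[g, "p2"],
      b_t1 = ct[b, "t1"], b_t2 = ct[b, "t2"], b_p1 = ct[b, "p1"],
      b_p2 = ct[b, "p2"],
      c_t1 = ct[g, "t1"], c_t2 = ct[b, "t2"], c_p1 = ct[g, "p1"],
      c_p2 = ct[b, "p2"]
    )[rep(1, n), ]
  }
  ev <- dplyr::bind_rows(mk_ev(1, 2, 20), mk_ev(2, 1, 25))
  te <- trace_event_graphs(ev, part)
  cg <- build_clan_graphs(part)
  expect_equal(te$marriage, cg$marriage)
  expect_equal(te$descent_paternal, cg$descent_paternal)
  expect_equal(te$descent_maternal, cg$descent_maternal)
  # a single marriage defines edges only for the involved clans
  te1 <- trace_event_graphs(mk_ev(1, 2, 1), part)
  expect_equal(te1$marriage, c(2L, NA))
  expect_error(trace_event_graphs(ev[0, ], part), "empty")
})
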