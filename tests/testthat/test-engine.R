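# The generational engine. Unit tests drive the pure-R reference phases on
# hand-built worlds; the compiled engine is pinned to the reference by exact
# trajectory equality under a shared seed.

test_that("initialization founds homogeneous societies and is seed-reproducible", {
  p <- kin_params(d_c = 1, d_m = 1, N_f = 5, N_s = 3, n_steps = 0, seed = 7)
  sim <- run_kinship_sim(p)
  expect_equal(nrow(sim$families), 15L)
  expect_equal(length(unique(sim$families$society_id)), 3L)
  expect_true(all(sim$families$t1 == 0 & sim$families$t2 == 0 &
                    sim$families$p1 == 0 & sim$families$p2 == 0))
  # all pairwise distances are zero at the founding state
  f1 <- sim$families[1, ]
  expect_equal(pair_distance(c(0, 0), c(0, 0), c(f1$t1, f1$t2),
                             c(f1$p1, f1$p2)), 0)
  sim2 <- run_kinship_sim(p)
  expect_identical(as.data.frame(sim$families), as.data.frame(sim2$families))
})

test_that("reproduction draws Poisson(r) sons and daughters, independently", {
  p <- kin_params(d_c = 0, d_m = 0, b = 5, N_f = 2, N_s = 1)
  n <- 1000L
  fams <- tibble::tibble(t1 = rep(0, n), t2 = 0, p1 = 0, p2 = 0,
                         has_repro = FALSE)
  w <- mk_world(p, list(fams))
  withr::with_seed(21, w2 <- kinevo:::step_reproduce_r(w, p))
  men <- vapply(w2$societies[[1]]$families, function(f) f$men[1], 0L)
  wom <- vapply(w2$societies[[1]]$families, function(f) f$women[1], 0L)
  # d_c = d_m = 0 gives r = b exactly; mean within 3 s.e.
  expect_lt(abs(mean(men) - 5), 3 * sqrt(5 / n))
  expect_lt(abs(mean(wom) - 5), 3 * sqrt(5 / n))
  expect_lt(abs(cor(men, wom)), 0.1)

  # identical families with competition: r = b * exp(-d_m)
  p2 <- kin_params(d_c = 2, d_m = 0.8, b = 5, N_f = 2, N_s = 1)
  withr::with_seed(22, w3 <- kinevo:::step_reproduce_r(mk_world(p2, list(fams)), p2))
  men3 <- vapply(w3$societies[[1]]$families, function(f) f$men[1], 0L)
  r_exp <- 5 * exp(-0.8)
  expect_lt(abs(mean(men3) - r_exp), 3 * sqrt(r_exp / n))
})

test_that("marriage is monogamous, conserves counts, and follows preferences", {
  p <- kin_params(d_c = 1, d_m = 1, N_f = 2, N_s = 1, mu = 0)
  # one man whose trait matches the one available bride family exactly (and
  # nobody else comes close) -> exactly one marriage, one new family
  fams <- tibble::tibble(t1 = c(0, 1), t2 = 0, p1 = c(50, 0), p2 = c(50, 0),
                         men0 = c(1L, 0L), wom0 = c(0L, 1L),
                         has_repro = TRUE)
  withr::with_seed(23, w2 <- kinevo:::step_marriage_r(mk_world(p, list(fams)), p))
  expect_equal(length(w2$events), 1L)
  expect_equal(length(w2$societies[[1]]$families), 3L)
  expect_equal(count_members(w2, "men"), 0L)
  expect_equal(count_members(w2, "women"), 0L)
  ev <- w2$events[[1]]
  expect_equal(ev$groom_family_id, 1L)
  expect_equal(ev$bride_family_id, 2L)
  # noise-free inheritance: paternal t1, maternal t2
  expect_equal(ev$c_t1, 0)
  expect_equal(ev$c_t2, 0)

  # marriages never exceed min(men, women); offers landing on families with
  # no available daughter fail and those men stay unmarried
  fams2 <- tibble::tibble(t1 = 0, t2 = 0, p1 = 0, p2 = 0,
                          men0 = c(5L, 3L), wom0 = c(2L, 0L),
                          has_repro = TRUE)
  withr::with_seed(24, w3 <- kinevo:::step_marriage_r(mk_world(p, list(fams2)), p))
  expect_lte(length(w3$events), 2L)
  expect_equal(count_members(w3, "men"), 8L - length(w3$events))

  # bride families chosen by exp(-|t_g - p_b|^2 / tau^2): a perfect match
  # against a 10-tau mismatch is picked essentially always
  fams3 <- tibble::tibble(t1 = c(0, 0, 0), t2 = 0, p1 = c(9, 0, 10), p2 = 0,
                          men0 = c(1L, 0L, 0L), wom0 = c(0L, 5L, 5L),
                          has_repro = TRUE)
  withr::with_seed(25, {
    picks <- replicate(300, {
      w <- kinevo:::step_marriage_r(mk_world(p, list(fams3)), p)
      w$events[[1]]$bride_family_id
    })
  })
  expect_true(all(picks == 2L))
})

test_that("unmarried individuals die after their allotted rounds; empty societies go extinct", {
  p <- kin_params(d_c = 1, d_m = 1, N_f = 2, N_s = 1)
  fams <- tibble::tibble(t1 = 0, t2 = 0, p1 = 0, p2 = 0,
                         men0 = 2L, men1 = 3L, wom0 = 1L,
                         has_repro = TRUE)
  w2 <- kinevo:::step_cull_r(mk_world(p, list(fams)), p)
  f <- w2$societies[[1]]$families[[1]]
  expect_equal(f$men, c(0L, 2L))   # age-0 men aged to 1; age-1 men died
  expect_equal(f$women, c(0L, 1L))
  # a family with nothing left and no pending birth disappears
  fams2 <- tibble::tibble(t1 = 0, t2 = 0, p1 = 0, p2 = 0, men1 = 1L,
                          has_repro = TRUE)
  w3 <- kinevo:::step_cull_r(mk_world(p, list(fams2)), p)
  expect_equal(length(w3$societies[[1]]$families), 0L)
  # but a newly founded family (pending first birth) is kept
  fams3 <- tibble::tibble(t1 = 0, t2 = 0, p1 = 0, p2 = 0, has_repro = FALSE)
  w4 <- kinevo:::step_cull_r(mk_world(p, list(fams3)), p)
  expect_equal(length(w4$societies[[1]]$families), 1L)
})

test_that("societies split in half at threshold and replace a random victim", {
  p <- kin_params(d_c = 1, d_m = 1, N_f = 4, N_s = 4)
  big <- tibble::tibble(t1 = seq_len(8), t2 = 0, p1 = 0, p2 = 0,
                        has_repro = FALSE)
  small <- tibble::tibble(t1 = 0, t2 = 0, p1 = 0, p2 = 0, has_repro = FALSE)
  w <- mk_world(p, list(big, small, small, small))
  withr::with_seed(26, w2 <- kinevo:::step_split_r(w, p))
  sizes <- vapply(w2$societies, function(s) length(s$families), 0L)
  expect_equal(length(w2$societies), 4L)
  expect_equal(sort(sizes, decreasing = TRUE)[1:2], c(4L, 4L))
  expect_equal(sum(sizes), 8L + 1L + 1L)  # one victim replaced
  expect_equal(length(w2$splits), 1L)
  # nothing happens below threshold
  w3 <- kinevo:::step_split_r(mk_world(p, list(small, small)), p)
  expect_equal(length(w3$splits), 0L)
  # the victim is uniform among the other societies
  withr::with_seed(27, {
    victims <- replicate(600, {
      ww <- kinevo:::step_split_r(mk_world(p, list(big, small, small, small)), p)
      ww$splits[[1]]$removed_id
    })
  })
  frac <- table(factor(victims, levels = 2:4)) / 600
  expect_true(all(abs(frac - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 600)))
})

test_that("the compiled engine reproduces the reference engine bit for bit", {
  for (s in c(1, 2, 3)) {
    p <- kin_params(d_c = 0.5, d_m = 1.0, N_f = 6, N_s = 4, n_steps = 15,
                    seed = s)
    a <- run_kinship_sim(p, engine = "cpp")
    b <- run_kinship_sim(p, engine = "r")
    expect_identical(as.data.frame(a$families), as.data.frame(b$families))
    expect_identical(as.data.frame(a$events), as.data.frame(b$events))
    expect_identical(as.data.frame(a$splits), as.data.frame(b$splits))
    expect_identical(a$outcome, b$outcome)
    expect_equal(as.data.frame(a$summary), as.data.frame(b$summary),
                 tolerance = 1e-12)
  }
  # the micro-scale case: 2 societies, 3 families, 2 steps
  p <- kin_params(d_c = 1, d_m = 0.3, N_f = 3, N_s = 2, n_steps = 2, seed = 9)
  a <- run_kinship_sim(p, engine = "cpp")
  b <- run_kinship_sim(p, engine = "r")
  expect_identical(as.data.frame(a$families), as.data.frame(b$families))
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
})

test_that("run-level invariants: society count, size cap, monogamy, determinism", {
  p <- kin_params(d_c = 0.3, d_m = 0.2, N_f = 8, N_s = 5, n_steps = 30,
                  seed = 4)
  sim <- run_kinship_sim(p)
  # society count fixed; per-society family count under the split threshold
  expect_lte(length(unique(sim$families$society_id)), 5L)
  expect_true(all(table(sim$families$society_id) <= 2 * p$N_f))
  expect_true(all(sim$summary$n_societies_alive <= 5L))
  # monogamy: a family's id appears as child exactly once
  expect_false(any(duplicated(sim$events$child_family_id)))
  # identical seed, identical trajectory
  sim2 <- run_kinship_sim(p)
  expect_identical(as.data.frame(sim$events), as.data.frame(sim2$events))

  # n_steps = 0 returns the founding world
  p0 <- kin_params(d_c = 1, d_m = 1, N_f = 3, N_s = 2, n_steps = 0, seed = 1)
  expect_equal(nrow(run_kinship_sim(p0)$families), 6L)

  # no noise, no pressure: traits stay at the origin
  pz <- kin_params(d_c = 0, d_m = 0, mu = 0, N_f = 4, N_s = 2, n_steps = 10,
                   seed = 2)
  simz <- run_kinship_sim(pz)
  expect_true(all(simz$families$t1 == 0 & simz$families$p2 == 0))

  # overwhelming mortality pressure drives the whole system extinct
  pe <- kin_params(d_c = 10, d_m = 10, N_f = 6, N_s = 4, n_steps = 40,
                   seed = 3)
  expect_equal(run_kinship_sim(pe)$outcome, "extinct")
})

test_that("traits and preferences diverge far beyond the mutation scale", {
  # in the structured regimes the final spread along some dimension must
  # exceed the per-generation noise by an order of magnitude
  vars <- vapply(1:10, function(s) {
    p <- kin_params(d_c = 0.3, d_m = 0.2, N_f = 15, N_s = 10, n_steps = 120,
                    seed = 100 + s)
    sim <- run_kinship_sim(p)
    tail_row <- sim$summary[nrow(sim$summary), ]
    max(tail_row$var_t1, tail_row$var_t2, tail_row$var_p1, tail_row$var_p2)
  }, 0)
  expect_gt(median(vars), 10 * 0.1^2)
})
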