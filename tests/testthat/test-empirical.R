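toy_table <- function() {
  tibble::tibble(
    society_id = paste0("S", 1:4),
    structure = c("dual_organization", "dual_organization",
                  "generalized_exchange", "generalized_exchange"),
    descent = "patrilineal",
    v1 = c(1, 2, 3, 6),
    v2 = c(10, NA, 30, 20),
    v3 = c(5, 5, 5, 5)
  )
}

test_that("z-scoring normalizes available values and drops constants", {
  expect_warning(norm <- normalize_variables(toy_table()), "constant")
  expect_false("v3" %in% names(norm))
  expect_equal(mean(norm$v1), 0, tolerance = 1e-12)
  expect_equal(var(norm$v1), 1, tolerance = 1e-12)
  # hand-computed z-scores: mean 3, sd sqrt(14/3)
  expect_equal(norm$v1, (c(1, 2, 3, 6) - 3) / sqrt(14 / 3), tolerance = 1e-12)
  # missing entries stay missing, others z-scored over the available ones
  expect_true(is.na(norm$v2[2]))
  expect_equal(mean(norm$v2, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("pressure estimates average signed variables and shift minima to zero", {
  map <- tibble::tibble(variable = c("v1", "v2"), target = c("d_c", "d_m"),
                        sign = c(1, 1))
  tab <- suppressWarnings(normalize_variables(toy_table()))
  est <- estimate_dc_dm(tab, map)
  expect_equal(min(est$dc_tilde), 0)
  expect_equal(min(est$dm_tilde, na.rm = TRUE), 0)
  # hand check: dc_tilde is the z-scored v1 shifted by its minimum
  z1 <- (c(1, 2, 3, 6) - 3) / sqrt(14 / 3)
  expect_equal(est$dc_tilde, z1 - min(z1), tolerance = 1e-12)
  # the society with a missing d_m variable gets NA
  expect_true(is.na(est$dm_tilde[2]))
  expect_true(all(c("structure", "descent") %in% names(est)))

  # averaging over several variables, by hand, with a missing cell
  tab2 <- tibble::tibble(society_id = c("a", "b", "c"),
                         x = c(1, 0, -1), y = c(0.5, NA, -0.5))
  map2 <- tibble::tibble(variable = c("x", "y"), target = "d_c",
                         sign = c(1, 1))
  est2 <- estimate_dc_dm(tab2, map2)
  pre <- c(mean(c(1, 0.5)), 0, mean(c(-1, -0.5)))
  expect_equal(est2$dc_tilde, pre - min(pre), tolerance = 1e-12)
})

test_that("sign flips in the mapping negate contributions exactly", {
  tab <- tibble::tibble(society_id = c("a", "b", "c"), x = c(1, 0, -2))
  plus <- estimate_dc_dm(tab, tibble::tibble(variable = "x", target = "d_c",
                                             sign = 1))
  minus <- estimate_dc_dm(tab, tibble::tibble(variable = "x", target = "d_c",
                                              sign = -1))
  expect_equal(minus$dc_tilde, max(tab$x) - tab$x)
  expect_equal(plus$dc_tilde + minus$dc_tilde,
               rep(diff(range(tab$x)), 3) - 0 * tab$x)
})

test_that("the pipeline is invariant to affine rescaling of raw variables", {
  fx <- make_sccs_table(n_societies = 60, seed = 41)
  raw <- fx$table
  scaled <- raw
  vars <- setdiff(names(raw), c("society_id", "structure", "descent"))
  for (i in seq_along(vars)) {
    scaled[[vars[i]]] <- scaled[[vars[i]]] * (i + 1) - 3 * i
  }
  est_a <- estimate_dc_dm(normalize_variables(raw), fx$mapping)
  est_b <- estimate_dc_dm(normalize_variables(scaled), fx$mapping)
  expect_equal(est_a$dc_tilde, est_b$dc_tilde, tolerance = 1e-12)
  expect_equal(est_a$dm_tilde, est_b$dm_tilde, tolerance = 1e-12)
})

test_that("Spearman pair correlations match the rank formula and detect separation", {
  # 6-society worked example, computed by hand via mid-ranked rank correlation
  tab <- tibble::tibble(
    society_id = paste0("S", 1:6),
    structure = rep(c("A", "B"), each = 3),
    v = c(1, 2, 2, 4, 5, 6)
  )
  res <- spearman_pair_correlations(tab)
  # ranks of v: 1, 2.5, 2.5, 4, 5, 6 against y = 0,0,0,1,1,1
  want <- cor(c(1, 2.5, 2.5, 4, 5, 6), c(1.5, 1.5, 1.5, 4.5, 4.5, 4.5))
  expect_equal(res$mean_abs_rho, abs(want), tolerance = 1e-12)

  # a variable that perfectly separates two classes has |rho| = 1... up to ties
  sep <- tibble::tibble(society_id = paste0("S", 1:8),
                        structure = rep(c("A", "B"), each = 4),
                        v = c(1:4, 11:14))
  expect_equal(spearman_pair_correlations(sep)$mean_abs_rho[1],
               cor(rank(sep$v), rank(rep(c(0, 1), each = 4))))
  # ... and a label-independent variable correlates near zero on average
  withr::with_seed(42, {
    rhos <- replicate(200, {
      noise <- tibble::tibble(society_id = paste0("S", 1:40),
                              structure = rep(c("A", "B"), each = 20),
                              v = rnorm(40))
      spearman_pair_correlations(noise)$mean_abs_rho
    })
  })
  expect_lt(mean(rhos), 0.2)
})

test_that("latent pressures are recovered from noisy synthetic tables", {
  fx <- make_sccs_table(n_societies = 150, noise_sd = 0.5, seed = 43)
  est <- estimate_dc_dm(normalize_variables(fx$table), fx$mapping)
  expect_gt(cor(est$dc_tilde, fx$latent$d_c, use = "complete.obs"), 0.8)
  expect_gt(cor(est$dm_tilde, fx$latent$d_m, use = "complete.obs"), 0.8)
  # noise-free recovery is a perfect rank correlation
  fx0 <- make_sccs_table(n_societies = 50, noise_sd = 0, missing_rate = 0,
                         seed = 44)
  est0 <- estimate_dc_dm(normalize_variables(fx0$table), fx0$mapping)
  expect_equal(cor(est0$dc_tilde, fx0$latent$d_c, method = "spearman"), 1)
})

test_that("the empirical phase table reproduces the ratio ordering of structures", {
  fx <- make_sccs_table(n_societies = 200, noise_sd = 0.3, seed = 45)
  est <- estimate_dc_dm(normalize_variables(fx$table), fx$mapping)
  pt <- empirical_phase_table(est)
  med <- pt$by_structure
  ord <- med$median_ratio[match(c("dual_organization", "generalized_exchange",
                                  "restricted_exchange"), med$structure)]
  expect_true(all(diff(ord) > 0))
  # destroying the labels destroys the ordering
  withr::with_seed(46, {
    broken <- est
    broken$structure <- sample(broken$structure)
    medb <- empirical_phase_table(broken)$by_structure
    ordb <- medb$median_ratio[match(c("dual_organization",
                                      "generalized_exchange",
                                      "restricted_exchange"),
                                    medb$structure)]
    expect_lt(diff(range(ordb)), diff(range(ord)))
  })
  # degenerate single-structure input yields a single summary row
  one <- est[est$structure == "dual_organization", ]
  expect_equal(nrow(empirical_phase_table(one)$by_structure), 1L)
})
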