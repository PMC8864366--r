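# Analytic phase-boundary condition between clan endogamy and dual
# organization.
#
# In clan endogamy every family is simultaneously kin and rival, so its growth
# factor is exp(-d_c * 0 - d_m * 1). In dual organization half the families
# are kin-and-rival and the other half are mates whose cooperation is reduced
# by the factor exp(-alpha * mu^2) (the groom and bride clan centres deviate
# by order mu), giving exp(-d_c * (1/2 - 1/2 exp(-alpha mu^2)) - d_m / 2).
# Weighting each side by the probability that the structure survives
# demographic fluctuation (p_C, p_D) yields the transition condition; dividing
# through by d_c puts it in ratio form.

check_analytic <- function(alpha, p_C, p_D, mu) {
  stopifnot(alpha >= 0, p_C > 0, p_C <= 1, p_D > 0, p_D <= 1, mu >= 0)
}

#' Is dual organization more adaptive than clan endogamy?
#'
#' Compares the sustenance-weighted growth factors of the two structures:
#' clan endogamy grows as `p_C * exp(-d_m)` while dual organization grows as
#' `p_D * exp(-d_c * (1/2 - exp(-alpha mu^2)/2) - d_m/2)`. Dual organization
#' is favoured when the second strictly exceeds the first.
#'
#' @param d_c,d_m Mortality pressures (>= 0).
#' @param alpha Deviation coefficient, O(1) (default 1).
#' @param p_C,p_D Sustenance probabilities of clan endogamy and dual
#'   organization, in (0, 1] (default 1 each).
#' @param mu Mutation scale (default 0.1).
#' @return A list: `dual_favoured` (logical), `endogamy_growth`,
#'   `dual_growth`.
#' @examples
#' dual_beats_endogamy(d_c = 1, d_m = 0.5)
#' @export
dual_beats_endogamy <- function(d_c, d_m, alpha = 1, p_C = 1, p_D = 1,
                                mu = 0.1) {
  check_analytic(alpha, p_C, p_D, mu)
  stopifnot(d_c >= 0, d_m >= 0)
  lhs <- p_C * exp(-d_m)
  rhs <- p_D * exp(-d_c * (0.5 - 0.5 * exp(-alpha * mu^2)) - d_m / 2)
  list(dual_favoured = lhs < rhs, endogamy_growth = lhs, dual_growth = rhs)
}

#' Critical d_m/d_c ratio for the endogamy-to-dual transition
#'
#' The transition condition in ratio form: dual organization is favoured when
#' `d_m / d_c > 1 - exp(-alpha mu^2) + (2 / d_c) * log(p_C / p_D)`. For large
#' `d_c` the bound approaches the constant `1 - exp(-alpha mu^2)`, so the
#' phase boundary is asymptotically a ray `d_m / d_c = C`.
#'
#' @inheritParams dual_beats_endogamy
#' @param d_c Must be > 0 (use [dual_beats_endogamy()] directly at d_c = 0).
#' @return The right-hand side of the ratio condition (scalar or vector along
#'   `d_c`).
#' @examples
#' threshold_ratio(d_c = 1, alpha = 1, mu = 0.1)  # ~ 1 - exp(-0.01)
#' @export
threshold_ratio <- function(d_c, alpha = 1, p_C = 1, p_D = 1, mu = 0.1) {
  check_analytic(alpha, p_C, p_D, mu)
  if (any(d_c <= 0)) abort("`d_c` must be positive in ratio form.")
  1 - exp(-alpha * mu^2) + (2 / d_c) * log(p_C / p_D)
}

#' Analytic phase-boundary curve
#'
#' Tabulates the critical `d_m` above which dual organization beats clan
#' endogamy, over a grid of `d_c` values:
#' `d_m* = d_c * (1 - exp(-alpha mu^2)) + 2 log(p_C / p_D)`.
#'
#' @inheritParams dual_beats_endogamy
#' @param d_c Positive numeric grid.
#' @return A tibble with `d_c`, `threshold_ratio`, `critical_d_m`.
#' @examples
#' boundary_curve(d_c = c(0.5, 1, 2, 5, 10))
#' @export
boundary_curve <- function(d_c, alpha = 1, p_C = 1, p_D = 1, mu = 0.1) {
  ratio <- threshold_ratio(d_c, alpha, p_C, p_D, mu)
  tibble::tibble(d_c = d_c, threshold_ratio = ratio,
                 critical_d_m = d_c * ratio)
}

#' Estimate a structure's sustenance probability by simulation
#'
#' Seeds runs from a constructed initial configuration of the given kind (a
#' [make_clan_cloud()] geometry) and reports the fraction of trials in which
#' the structure is still classified at step `n_steps`. This is a utility for
#' supplying `p_C` / `p_D` to the boundary condition empirically; it is a
#' Monte Carlo estimate, not a closed form.
#'
#' @param kind Passed to [make_clan_cloud()].
#' @param params A [kin_params()] object (its `N_f` families per society are
#'   drawn from the constructed cloud).
#' @param n_trials Number of independent trials.
#' @param base_seed Seed for the first trial; trial i uses `base_seed + i - 1`.
#' @return Fraction of trials in which the classified structure equals the
#'   seeded one.
#' @export
estimate_sustenance <- function(kind, params, n_trials = 10L, base_seed = 1L) {
  cloud <- make_clan_cloud(kind = kind, seed = base_seed)
  target <- cloud$truth$structure
  hits <- 0L
  for (i in seq_len(n_trials)) {
    p_i <- params
    p_i$seed <- as.integer(base_seed + i - 1L)
    sim <- run_kinship_sim(p_i, init = cloud$points)
    cls <- classify_kinship(sim, tau = params$tau, seed = p_i$seed)
    if (identical(cls$structure, target)) hits <- hits + 1L
  }
  hits / n_trials
}
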