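#' Family-pair distance underlying cooperation
#'
#' The distance between families i and j used for the cooperation kernel is the
#' minimum of three Euclidean distances: trait-to-trait |t_i - t_j| (cultural
#' kin), and the two cross terms |p_i - t_j| and |t_i - p_j| (one family
#' preferring the other's traits, i.e. mates). It is symmetric in (i, j).
#'
#' @param t_i,t_j Numeric length-2 trait vectors.
#' @param p_i,p_j Numeric length-2 preference vectors.
#' @return A non-negative scalar.
#' @examples
#' pair_distance(c(0, 0), c(3, 0), c(5, 0), c(9, 9))
#' @export
pair_distance <- function(t_i, p_i, t_j, p_j) {
  stopifnot(all(is.finite(c(t_i, p_i, t_j, p_j))))
  e2 <- function(a, b) sqrt(sum((a - b)^2))
  min(e2(t_i, t_j), e2(p_i, t_j), e2(t_i, p_j))
}

#' Cooperation and competition kernels
#'
#' `cooperation_degree()` is the Gaussian kernel exp(-d^2 / tau^2) of
#' [pair_distance()]; `competition_degree()` is the same kernel applied to the
#' preference distance |p_i - p_j| only (families with similar preferences are
#' mating rivals regardless of their traits).
#'
#' @inheritParams pair_distance
#' @param tau Tolerance bandwidth (> 0).
#' @return A scalar in (0, 1]; equals 1 iff the relevant distance is 0.
#' @export
cooperation_degree <- function(t_i, p_i, t_j, p_j, tau) {
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be a positive number.")
  d <- pair_distance(t_i, p_i, t_j, p_j)
  exp(-d^2 / tau^2)
}

#' @rdname cooperation_degree
#' @export
competition_degree <- function(p_i, p_j, tau) {
  if (!is.numeric(tau) || tau <= 0) abort("`tau` must be a positive number.")
  exp(-sum((p_i - p_j)^2) / tau^2)
}

# internal: validate a families tibble (columns t1,t2,p1,p2)
check_families <- function(families) {
  need <- c("t1", "t2", "p1", "p2")
  if (!all(need %in% names(families))) {
    abort("`families` must have columns t1, t2, p1, p2.")
  }
  if (nrow(families) == 0L) {
    abort("`families` is empty; an extinct society has no interaction profile.")
  }
  families
}

#' Interaction profile of every family in a society
#'
#' For each family i in the society roster, computes the density of cooperative
#' families `friend_i` (mean cooperation kernel over all families j in the
#' society, the self-term j = i included, contributing 1), the density of
#' competitive families `rival_i` (mean competition kernel), and the expected
#' per-sex offspring count
#' `r_i = b * exp(-d_c * (1 - friend_i) - d_m * rival_i)`.
#'
#' @param families A data frame with one row per family and numeric columns
#'   `t1`, `t2`, `p1`, `p2`.
#' @param params A [kin_params()] object (uses `tau`, `b`, `d_c`, `d_m`).
#' @return `families` as a tibble with columns `friend`, `rival`, `r` appended.
#' @examples
#' fams <- tibble::tibble(t1 = 0, t2 = 0, p1 = 0, p2 = 0)[rep(1, 4), ]
#' interaction_profile(fams, kin_params(d_c = 1, d_m = 0.5))
#' @export
interaction_profile <- function(families, params) {
  check_families(families)
  tau2 <- params$tau^2
  t1 <- families$t1; t2 <- families$t2
  p1 <- families$p1; p2 <- families$p2
  dtt <- outer(t1, t1, "-")^2 + outer(t2, t2, "-")^2
  dpp <- outer(p1, p1, "-")^2 + outer(p2, p2, "-")^2
  dtp <- outer(t1, p1, "-")^2 + outer(t2, p2, "-")^2 # [i,j] = |t_i - p_j|^2
  dmin <- pmin(dtt, dtp, t(dtp))
  friend <- rowMeans(exp(-dmin / tau2))
  rival <- rowMeans(exp(-dpp / tau2))
  r <- params$b * exp(-params$d_c * (1 - friend) - params$d_m * rival)
  tibble::as_tibble(families) %>%
    mutate(friend = friend, rival = rival, r = r)
}

#' Marriage-offer distribution for one groom family
#'
#' The probability that men of family i marry women of family j is proportional
#' to exp(-|t_i - p_j|^2 / tau^2): the bride family's preference vector is
#' matched against the groom family's trait vector. The groom's own family is a
#' legal target (no hard-coded incest prohibition). If every weight underflows
#' to zero the distribution falls back to uniform so that marriage remains
#' possible in pathologically spread-out states.
#'
#' @param t_i Length-2 trait vector of the groom family.
#' @param families Data frame of candidate bride families (columns `p1`, `p2`).
#' @param tau Tolerance bandwidth.
#' @return A probability vector over the rows of `families` (sums to 1).
#' @export
marriage_offer_distribution <- function(t_i, families, tau) {
  if (nrow(families) == 0L) abort("no candidate bride families.")
  w <- exp(-((t_i[1] - families$p1)^2 + (t_i[2] - families$p2)^2) / tau^2)
  s <- sum(w)
  if (s <= 0) rep(1 / nrow(families), nrow(families)) else w / s
}

#' Cultural transmission to a child family
#'
#' A child family founded by a man of the groom family and a woman of the bride
#' family inherits the paternal components (t1, p1) from the groom family and
#' the maternal components (t2, p2) from the bride family, each perturbed by
#' independent Gaussian noise with standard deviation `mu`.
#'
#' @param groom,bride Lists or one-row data frames with fields `t1`, `t2`,
#'   `p1`, `p2`.
#' @param mu Mutation scale (noise SD per component).
#' @return A list with numeric fields `t1`, `t2`, `p1`, `p2`. Consumes four
#'   normal deviates from the R RNG in the order t1, t2, p1, p2.
#' @export
inherit <- function(groom, bride, mu) {
  eta <- rnorm(4L)
  list(
    t1 = groom$t1 + mu * eta[1],
    t2 = bride$t2 + mu * eta[2],
    p1 = groom$p1 + mu * eta[3],
    p2 = bride$p2 + mu * eta[4]
  )
}
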