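# Synthetic fixtures: clan point clouds with known ground truth, and
# SCCS-style ethnographic tables with known latent pressures. These are
# first-class generators used by the test suite and available to users for
# calibration experiments.

#' Synthetic clan configuration with known structure
#'
#' Places clan centroids in (t1, t2, p1, p2) so that each clan's preference
#' vector equals the trait vector of its marriage target and the assembled
#' child vector (paternal t1/p1, maternal t2/p2) lands in the descent-target
#' clan, then scatters `n_per_clan` families around each centroid with
#' isotropic Gaussian noise. The implied ground-truth classification is
#' returned alongside the points.
#'
#' Geometries: `"endogamy"` is a single self-preferring clan; `"dual"` is two
#' clans exchanging brides directly, separated along the axis given by
#' `descent_axis` ("t1" gives patrilineal, "t2" matrilineal); `"generalized"`
#' is `k >= 3` clans preferring each other cyclically along one axis;
#' `"restricted"` is the 2 x 2 grid of four clans with pairwise marriage and
#' descent relationships (double descent, so `descent_axis` must be "both").
#'
#' @param kind One of "endogamy", "dual", "generalized", "restricted".
#' @param k Number of clans for `kind = "generalized"` (>= 3; default 3).
#' @param n_per_clan Families per clan (default 30).
#' @param separation Centroid spacing in units of `tau` (default 5).
#' @param noise_sd Within-clan standard deviation in units of `tau`
#'   (default 0.1).
#' @param descent_axis "t1", "t2" or "both"; which trait dimension(s) the
#'   clans diverge along. Defaults: "t2" for dual (the matrilineal pattern),
#'   "t1" for generalized (patrilineal), "both" for restricted.
#' @param tau Tolerance unit (default 1).
#' @param seed Optional integer seed (private RNG stream).
#' @return A list: `points` (tibble t1, t2, p1, p2, clan), `centroids`,
#'   `truth` (one-row tibble: structure, descent_system, C_m, C_d, n_clans).
#' @examples
#' make_clan_cloud(kind = "restricted", seed = 1)$truth
#' @export
make_clan_cloud <- function(kind = c("endogamy", "dual", "generalized",
                                     "restricted"),
                            k = 3L, n_per_clan = 30L, separation = 5,
                            noise_sd = 0.1, descent_axis = NULL, tau = 1.0,
                            seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(separation > 0, noise_sd >= 0, n_per_clan >= 1)
  if (is.null(descent_axis)) {
    descent_axis <- switch(kind, endogamy = "t1", dual = "t2",
                           generalized = "t1", restricted = "both")
  }
  descent_axis <- match.arg(descent_axis, c("t1", "t2", "both"))
  s <- separation * tau
  ax <- function(along, j) if (along == "t1") c(j * s, 0) else c(0, j * s)

  if (kind == "endogamy") {
    tmat <- matrix(0, 1, 2)
    pmat <- tmat
    truth <- tibble::tibble(structure = "clan_endogamy",
                            descent_system = "undivided",
                            C_m = 1L, C_d = 1L, n_clans = 1L)
  } else if (kind == "dual") {
    if (descent_axis == "both")
      abort("dual organization is unilineal; descent_axis cannot be 'both'.")
    tmat <- rbind(ax(descent_axis, 0), ax(descent_axis, 1))
    pmat <- tmat[c(2, 1), , drop = FALSE]
    truth <- tibble::tibble(
      structure = "dual_organization",
      descent_system = if (descent_axis == "t1") "patrilineal" else "matrilineal",
      C_m = 2L, C_d = 1L, n_clans = 2L)
  } else if (kind == "generalized") {
    if (descent_axis == "both")
      abort("generalized exchange is unilineal; descent_axis cannot be 'both'.")
    k <- as.integer(k)
    if (k < 3L) abort("generalized exchange needs k >= 3 clans.")
    tmat <- t(vapply(seq_len(k) - 1L, ax, numeric(2), along = descent_axis))
    pmat <- tmat[c(seq_len(k)[-1L], 1L), , drop = FALSE]  # women of j prefer j+1
    truth <- tibble::tibble(
      structure = "generalized_exchange",
      descent_system = if (descent_axis == "t1") "patrilineal" else "matrilineal",
      C_m = k, C_d = 1L, n_clans = k)
  } else {  # restricted
    if (descent_axis != "both")
      abort("restricted exchange has double descent; use descent_axis = 'both'.")
    # clans A1, A2, B1, B2 on a 2 x 2 grid in (t1, t2)
    tmat <- rbind(c(0, 0), c(0, s), c(s, 0), c(s, s))
    # marriage A1 <=> B2, A2 <=> B1
    pmat <- tmat[c(4, 3, 2, 1), , drop = FALSE]
    truth <- tibble::tibble(structure = "restricted_exchange",
                            descent_system = "double",
                            C_m = 2L, C_d = 2L, n_clans = 4L)
  }

  centroids <- cbind(t1 = tmat[, 1], t2 = tmat[, 2],
                     p1 = pmat[, 1], p2 = pmat[, 2])
  nclan <- nrow(centroids)
  pts <- with_local_seed(seed, {
    idx <- rep(seq_len(nclan), each = n_per_clan)
    noise <- matrix(rnorm(4L * length(idx), sd = noise_sd * tau),
                    ncol = 4L)
    tibble::tibble(
      t1 = centroids[idx, "t1"] + noise[, 1],
      t2 = centroids[idx, "t2"] + noise[, 2],
      p1 = centroids[idx, "p1"] + noise[, 3],
      p2 = centroids[idx, "p2"] + noise[, 4],
      clan = idx
    )
  })
  list(points = pts, centroids = centroids, truth = truth)
}

#' Synthetic SCCS-style ethnographic table
#'
#' Emulates the cross-cultural data layout used by the empirical pipeline:
#' societies carry latent cooperation/competition pressures (d_c, d_m), the
#' observed indicator variables are noisy signed linear readouts of the
#' relevant latent pressure, some cells are missing, and the kinship-structure
#' label follows the theoretical ordering of structures in d_m / d_c.
#'
#' @param n_societies Number of societies (>= 10; default 150).
#' @param mapping A variable mapping tibble (`variable`, `target`, `sign`);
#'   default [sccs_default_mapping()]. One observed column per row.
#' @param loading Scale of the linear readout (default 1).
#' @param noise_sd Observation noise SD (default 0.5).
#' @param missing_rate Probability that any one cell is missing (default 0.1).
#' @param phase_breaks Increasing d_m/d_c ratio cut points separating clan
#'   endogamy / dual organization / generalized exchange / restricted
#'   exchange (default `c(0.1, 0.45, 1.2)`).
#' @param seed Optional integer seed (private RNG stream).
#' @return A list: `table` (society_id, structure, descent, one column per
#'   variable with NAs for missing cells), `latent` (society_id, d_c, d_m,
#'   ratio), and the `mapping` used.
#' @examples
#' fx <- make_sccs_table(n_societies = 30, seed = 1)
#' head(fx$table)
#' @export
make_sccs_table <- function(n_societies = 150L,
                            mapping = sccs_default_mapping(),
                            loading = 1, noise_sd = 0.5, missing_rate = 0.1,
                            phase_breaks = c(0.1, 0.45, 1.2), seed = NULL) {
  stopifnot(n_societies >= 10L, noise_sd >= 0, missing_rate >= 0,
            missing_rate < 1, length(phase_breaks) == 3L,
            !is.unsorted(phase_breaks))
  with_local_seed(seed, {
    d_c <- runif(n_societies, 0.2, 5)
    d_m <- runif(n_societies, 0.02, 2)
    ratio <- d_m / d_c
    structure <- cut(ratio, breaks = c(-Inf, phase_breaks, Inf),
                     labels = c("clan_endogamy", "dual_organization",
                                "generalized_exchange", "restricted_exchange"))
    descent <- ifelse(structure == "restricted_exchange", "double",
                      sample(c("patrilineal", "matrilineal"), n_societies,
                             replace = TRUE, prob = c(0.75, 0.25)))
    tab <- tibble::tibble(society_id = sprintf("S%03d", seq_len(n_societies)),
                          structure = as.character(structure),
                          descent = descent)
    for (i in seq_len(nrow(mapping))) {
      latent <- if (mapping$target[i] == "d_c") d_c else d_m
      v <- mapping$sign[i] * loading * latent + rnorm(n_societies, 0, noise_sd)
      v[runif(n_societies) < missing_rate] <- NA_real_
      tab[[mapping$variable[i]]] <- v
    }
    list(table = tab,
         latent = tibble::tibble(society_id = tab$society_id,
                                 d_c = d_c, d_m = d_m, ratio = ratio),
         mapping = mapping)
  })
}
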