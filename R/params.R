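#' Simulation parameters
#'
#' Bundles every model parameter together with the run controls. Defaults are
#' the reference values used throughout: intrinsic growth rate `b = 5`,
#' mutation scale `mu = 0.1`, similarity tolerance `tau = 1`, `N_f = 50`
#' founding families in each of `N_s = 50` societies. The two mortality
#' parameters `d_c` (death-rate increase from lack of cooperation) and `d_m`
#' (death-rate increase from mating competition) are the environmental axes of
#' the phase diagram and have no meaningful default, so they must be supplied.
#'
#' @param d_c Mortality increase from non-cooperation (>= 0).
#' @param d_m Mortality increase from mating competition (>= 0).
#' @param b Intrinsic growth rate (> 0).
#' @param mu Mutation scale: the standard deviation of the Gaussian noise added
#'   to each trait/preference component at cultural transmission (>= 0).
#' @param tau Tolerance for similarity of traits and preferences (> 0). All
#'   interaction kernels are Gaussian with bandwidth `tau`.
#' @param N_f Initial number of families per society (integer >= 2). A society
#'   splits when it reaches `split_threshold_factor * N_f` families.
#' @param N_s Number of societies in the system (integer >= 1); held fixed by
#'   the split-and-replace rule.
#' @param n_steps Number of generations to simulate.
#' @param seed Integer RNG seed, or `NULL` to continue from the current RNG
#'   state.
#' @param unmarried_lifespan Number of marriage rounds an individual may attend
#'   before dying unmarried (default 2).
#' @param split_threshold_factor A society splits in half upon reaching
#'   `split_threshold_factor * N_f` families (default 2).
#' @param event_window How many trailing generations of marriage events to
#'   retain in the returned event log (default 5).
#'
#' @return A list of class `kin_params`.
#' @examples
#' kin_params(d_c = 5, d_m = 0.1, n_steps = 100)
#' @export
kin_params <- function(d_c, d_m, b = 5.0, mu = 0.1, tau = 1.0,
                       N_f = 50L, N_s = 50L, n_steps = 500L, seed = NULL,
                       unmarried_lifespan = 2L, split_threshold_factor = 2,
                       event_window = 5L) {
  stopifnot(
    is.numeric(d_c), length(d_c) == 1L, d_c >= 0,
    is.numeric(d_m), length(d_m) == 1L, d_m >= 0,
    is.numeric(b), b > 0,
    is.numeric(mu), mu >= 0,
    is.numeric(tau), tau > 0,
    N_f >= 2, N_s >= 1, n_steps >= 0,
    unmarried_lifespan >= 1, split_threshold_factor > 0,
    event_window >= 0
  )
  p <- list(
    d_c = as.numeric(d_c), d_m = as.numeric(d_m),
    b = as.numeric(b), mu = as.numeric(mu), tau = as.numeric(tau),
    N_f = as.integer(N_f), N_s = as.integer(N_s),
    n_steps = as.integer(n_steps),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    unmarried_lifespan = as.integer(unmarried_lifespan),
    split_threshold_factor = as.numeric(split_threshold_factor),
    event_window = as.integer(event_window)
  )
  structure(p, class = "kin_params")
}

#' @export
print.kin_params <- function(x, ...) {
  cat("<kin_params>\n")
  cat(sprintf("  d_c = %g, d_m = %g\n", x$d_c, x$d_m))
  cat(sprintf("  b = %g, mu = %g, tau = %g\n", x$b, x$mu, x$tau))
  cat(sprintf("  N_f = %d, N_s = %d, n_steps = %d, seed = %s\n",
              x$N_f, x$N_s, x$n_steps,
              if (is.null(x$seed)) "<current RNG>" else x$seed))
  invisible(x)
}

# split threshold in family counts
split_threshold <- function(params) {
  params$split_threshold_factor * params$N_f
}
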