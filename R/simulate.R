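new_kinship_sim <- function(families, events, summary, outcome, final_step,
                            params, splits = NULL) {
  structure(
    list(families = tibble::as_tibble(families),
         events = tibble::as_tibble(events),
         summary = tibble::as_tibble(summary),
         splits = if (is.null(splits)) tibble::tibble() else
           tibble::as_tibble(splits),
         outcome = outcome, final_step = final_step, params = params),
    class = "kinship_sim"
  )
}

#' Marriage events along one society's lineage
#'
#' Societies split and get renamed over the course of a run, so the trailing
#' event log of the society that ends up as `society_id` is spread over its
#' ancestor ids. Walks the split log backwards to collect those ids and
#' returns the matching events.
#'
#' @param sim A `kinship_sim` object.
#' @param society_id The final society of interest (default: most populous).
#' @return The subset of `sim$events` belonging to the society's lineage.
#' @export
lineage_events <- function(sim, society_id = NULL) {
  stopifnot(inherits(sim, "kinship_sim"))
  if (is.null(society_id)) {
    soc <- largest_society(sim)
    if (nrow(soc) == 0L) return(sim$events[0L, ])
    society_id <- soc$society_id[1L]
  }
  anc <- society_id
  if (nrow(sim$splits) > 0L) {
    for (i in rev(seq_len(nrow(sim$splits)))) {
      if (sim$splits$child_id[i] %in% anc) {
        anc <- c(anc, sim$splits$parent_id[i])
      }
    }
  }
  filter(sim$events, .data$society_id %in% anc)
}

#' Run the multi-level kinship simulation
#'
#' Simulates `N_s` competing societies of families for `n_steps` generations.
#' Each generation: (i) every newly founded family draws unmarried sons and
#' daughters from a Poisson law whose mean depends on its densities of
#' cooperators and rivals; (ii) men, in random order, sample a bride family
#' with probability proportional to the Gaussian match between their family
#' trait and the candidate's preference, and each couple founds a child family
#' inheriting paternal (t1, p1) and maternal (t2, p2) components with
#' mutation; (iii) individuals unmarried for `unmarried_lifespan` rounds die
#' and empty families disappear; (iv) societies that doubled their founding
#' size split in half, each split deleting one other society at random so the
#' society count stays fixed.
#'
#' The default engine is compiled; `engine = "r"` runs the pure-R reference
#' transliteration of the same algorithm. Both consume the R RNG in the same
#' order, so for a given `seed` they return bit-identical trajectories.
#'
#' @param params A [kin_params()] object.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @param init Optional data frame or matrix of founding trait/preference
#'   vectors (columns t1, t2, p1, p2), recycled over the `N_f` founding
#'   families of every society; the default founds all families at the
#'   culturally homogeneous origin (0, 0, 0, 0). Useful for measuring how well
#'   a pre-built configuration sustains itself.
#' @return An object of class `kinship_sim`: a list with tibbles `families`
#'   (final roster: society_id, family_id, t1, t2, p1, p2, n_men, n_women),
#'   `events` (marriage log of the trailing `event_window` generations,
#'   including the trait/preference coordinates of groom, bride and child
#'   families), `summary` (per-generation family counts, population and trait
#'   variances), plus `outcome` ("completed" or "extinct"), `final_step`, and
#'   the parameters.
#' @examples
#' sim <- run_kinship_sim(kin_params(d_c = 0.3, d_m = 0.2, N_f = 10, N_s = 5,
#'                                   n_steps = 20, seed = 1))
#' glance(sim)
#' @export
run_kinship_sim <- function(params, engine = c("cpp", "r"), init = NULL) {
  stopifnot(inherits(params, "kin_params"))
  engine <- match.arg(engine)
  if (!is.null(init)) {
    init <- points_matrix(init)
    storage.mode(init) <- "double"
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  if (engine == "r") return(run_engine_r(params, init))
  res <- .run_engine_cpp(unclass(params), init)
  new_kinship_sim(res$families, res$events, res$summary, res$outcome,
                  res$final_step, params, res$splits)
}

#' @export
print.kinship_sim <- function(x, ...) {
  cat(sprintf("<kinship_sim> %s after %d step(s)\n", x$outcome, x$final_step))
  cat(sprintf("  d_c = %g, d_m = %g; %d societies, %d families\n",
              x$params$d_c, x$params$d_m, x$params$N_s, nrow(x$families)))
  invisible(x)
}

#' @describeIn run_kinship_sim Per-generation summary trajectory as a tibble.
#' @param x A `kinship_sim` object.
#' @param ... Unused.
#' @export
tidy.kinship_sim <- function(x, ...) x$summary

#' @describeIn run_kinship_sim One-row run summary.
#' @export
glance.kinship_sim <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, final_step = x$final_step,
    n_families = nrow(x$families),
    n_societies_alive = length(unique(x$families$society_id)),
    d_c = x$params$d_c, d_m = x$params$d_m
  )
}

#' @describeIn run_kinship_sim Trajectory plot of population size and trait
#'   variance per dimension.
#' @param object A `kinship_sim` object.
#' @export
autoplot.kinship_sim <- function(object, ...) {
  long <- object$summary %>%
    select("step", "var_t1", "var_t2", "var_p1", "var_p2") %>%
    tidyr::pivot_longer(-"step", names_to = "dimension",
                        values_to = "variance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$variance,
                                     colour = .data$dimension)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "system-wide variance",
                  title = "Divergence of traits and preferences") +
    ggplot2::theme_minimal()
}

#' Families of the most populous surviving society
#'
#' Convenience accessor used before classification: a single society's final
#' point cloud, chosen as the society with the most families (ties broken by
#' lowest society id).
#'
#' @param sim A `kinship_sim` object.
#' @return A tibble of families, or an empty tibble if all societies died out.
#' @export
largest_society <- function(sim) {
  stopifnot(inherits(sim, "kinship_sim"))
  if (nrow(sim$families) == 0L) return(sim$families)
  top <- sim$families %>%
    count(.data$society_id) %>%
    arrange(desc(.data$n), .data$society_id) %>%
    slice(1L) %>%
    pull("society_id")
  filter(sim$families, .data$society_id == top)
}
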