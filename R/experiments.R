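# Phase-diagram experiments: repeated simulations over a (d_c, d_m) grid,
# classification of every final state, and tabulation of structure and
# descent-system frequencies per cell.

structure_levels <- c("clan_endogamy", "dual_organization",
                      "generalized_exchange", "restricted_exchange",
                      "other", "extinct")
descent_levels <- c("patrilineal", "matrilineal", "double", "undivided",
                    "ambiguous", "extinct")

run_one_trial <- function(d_c, d_m, base, seed, theta, k_max) {
  p <- base
  p$d_c <- as.numeric(d_c)
  p$d_m <- as.numeric(d_m)
  p$seed <- as.integer(seed)
  sim <- run_kinship_sim(p)
  cls <- classify_kinship(sim, tau = p$tau, theta = theta, k_max = k_max,
                          seed = seed)
  tibble::tibble(
    d_c = p$d_c, d_m = p$d_m, seed = seed,
    outcome = sim$outcome,
    structure = cls$structure, descent_system = cls$descent_system,
    C_m = cls$C_m, C_d = cls$C_d, n_clans = cls$k,
    inconsistent = cls$inconsistent
  )
}

# modal structure of a cell: extinct runs are set aside unless extinction
# beats every emergent class outright; ties go lexicographic and are flagged
modal_structure <- function(structure) {
  tab <- table(factor(structure, levels = structure_levels))
  emergent <- tab[setdiff(names(tab), "extinct")]
  if (sum(emergent) == 0L || tab[["extinct"]] > max(emergent)) {
    return(list(modal = "extinct", tied = FALSE))
  }
  top <- emergent[emergent == max(emergent)]
  list(modal = sort(names(top))[1L], tied = length(top) > 1L)
}

summarise_cells <- function(runs, by) {
  runs %>%
    group_by(across(all_of(by))) %>%
    summarise(
      n_trials = n(),
      count_endogamy = sum(.data$structure == "clan_endogamy"),
      count_dual = sum(.data$structure == "dual_organization"),
      count_generalized = sum(.data$structure == "generalized_exchange"),
      count_restricted = sum(.data$structure == "restricted_exchange"),
      count_other = sum(.data$structure == "other"),
      count_extinct = sum(.data$structure == "extinct"),
      count_patrilineal = sum(.data$descent_system == "patrilineal"),
      count_matrilineal = sum(.data$descent_system == "matrilineal"),
      count_double = sum(.data$descent_system == "double"),
      modal_structure = modal_structure(.data$structure)$modal,
      modal_tied = modal_structure(.data$structure)$tied,
      extinct_fraction = mean(.data$structure == "extinct"),
      .groups = "drop"
    )
}

#' Phase-diagram sweep over (d_c, d_m)
#'
#' Runs `n_trials` independent simulations for every row of `grid`, classifies
#' the most populous surviving society of each run, and tabulates structure
#' and descent-system frequencies per cell together with the modal structure
#' (the class plotted in a phase diagram). Extinct runs count toward
#' `extinct_fraction` and only become the modal class when extinction is more
#' frequent than every emergent structure.
#'
#' @param grid A data frame with numeric columns `d_c` and `d_m`, one row per
#'   phase-diagram cell.
#' @param base A [kin_params()] object providing all other parameters
#'   (`d_c`/`d_m` and `seed` are overwritten per trial).
#' @param n_trials Simulations per cell (default 20).
#' @param base_seed Trial j of cell i runs with seed
#'   `base_seed + (i - 1) * n_trials + (j - 1)`.
#' @param theta,k_max Classifier settings, see [classify_kinship()].
#' @return A `phase_sweep` object: list with `cells` (per-cell counts and
#'   modal class) and `runs` (one row per simulation). `tidy()` returns the
#'   cells, `autoplot()` draws the modal-class map.
#' @examples
#' \donttest{
#' grid <- tidyr::crossing(d_c = c(0.3, 5), d_m = c(0.1, 0.2))
#' sw <- run_phase_sweep(grid, kin_params(d_c = 1, d_m = 1, N_f = 15,
#'                                        N_s = 10, n_steps = 100),
#'                       n_trials = 3)
#' tidy(sw)
#' }
#' @export
run_phase_sweep <- function(grid, base, n_trials = 20L, base_seed = 1L,
                            theta = 1.0, k_max = 8L) {
  stopifnot(inherits(base, "kin_params"), n_trials >= 1L,
            all(c("d_c", "d_m") %in% names(grid)))
  runs <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    purrr::map_dfr(seq_len(n_trials), function(j) {
      seed <- base_seed + (i - 1L) * n_trials + (j - 1L)
      run_one_trial(grid$d_c[i], grid$d_m[i], base, seed, theta, k_max)
    })
  })
  cells <- summarise_cells(runs, c("d_c", "d_m"))
  structure(list(cells = cells, runs = runs, base = base,
                 n_trials = n_trials, base_seed = base_seed),
            class = "phase_sweep")
}

#' @export
print.phase_sweep <- function(x, ...) {
  cat(sprintf("<phase_sweep> %d cells x %d trials\n", nrow(x$cells),
              x$n_trials))
  print(select(x$cells, "d_c", "d_m", "modal_structure", "extinct_fraction"))
  invisible(x)
}

#' @describeIn run_phase_sweep Per-cell tabulation as a tibble.
#' @param x A `phase_sweep` object.
#' @param ... Unused.
#' @export
tidy.phase_sweep <- function(x, ...) x$cells

#' @describeIn run_phase_sweep Modal-class phase-diagram tile map.
#' @param object A `phase_sweep` object.
#' @export
autoplot.phase_sweep <- function(object, ...) {
  cells <- mutate(object$cells,
                  modal_structure = factor(.data$modal_structure,
                                           levels = structure_levels))
  ggplot2::ggplot(cells, ggplot2::aes(x = factor(.data$d_c),
                                      y = factor(.data$d_m),
                                      fill = .data$modal_structure)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(clan_endogamy = "#e6c229", dual_organization = "#60a917",
                 generalized_exchange = "#e07a1f",
                 restricted_exchange = "#e75fa0",
                 other = "grey60", extinct = "#4575b4"),
      drop = FALSE) +
    ggplot2::labs(x = "d_c (non-cooperation mortality)",
                  y = "d_m (competition mortality)",
                  fill = "modal structure") +
    ggplot2::theme_minimal()
}

#' Modal structure and its cycle lengths per sweep cell
#'
#' For each cell of a sweep, reports the modal structure class together with
#' the modal marriage and descent cycle lengths among the runs of that class
#' (ties broken toward the smaller cycle) — the quantities a phase diagram is
#' built from.
#'
#' @param sweep A `phase_sweep` object.
#' @return A tibble with one row per cell: `d_c`, `d_m`, `modal_structure`,
#'   `n_modal`, `C_m`, `C_d`.
#' @export
modal_cycle_summary <- function(sweep) {
  stopifnot(inherits(sweep, "phase_sweep"))
  modal_int <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_integer_)
    tb <- table(x)
    as.integer(names(tb)[tb == max(tb)][1L])
  }
  sweep$runs %>%
    group_by(.data$d_c, .data$d_m) %>%
    summarise(
      modal_structure = modal_structure(.data$structure)$modal,
      n_modal = sum(.data$structure == modal_structure(.data$structure)$modal),
      C_m = modal_int(.data$C_m[.data$structure ==
                                  modal_structure(.data$structure)$modal]),
      C_d = modal_int(.data$C_d[.data$structure ==
                                  modal_structure(.data$structure)$modal]),
      .groups = "drop"
    )
}

#' Descent-system frequencies per kinship structure
#'
#' For every emergent structure class in a sweep, the fractions of runs with
#' patrilineal, matrilineal and double descent. The remainder up to 1 are
#' undivided/ambiguous runs.
#'
#' @param sweep A `phase_sweep` object (or its `runs` tibble).
#' @return A tibble with one row per structure class.
#' @export
descent_frequency_table <- function(sweep) {
  runs <- if (inherits(sweep, "phase_sweep")) sweep$runs else sweep
  runs <- filter(runs, .data$structure != "extinct")
  if (nrow(runs) == 0L) abort("no non-extinct classified runs in the sweep.")
  runs %>%
    group_by(structure = factor(.data$structure,
                                levels = setdiff(structure_levels,
                                                 "extinct"))) %>%
    summarise(
      n = n(),
      frac_patrilineal = mean(.data$descent_system == "patrilineal"),
      frac_matrilineal = mean(.data$descent_system == "matrilineal"),
      frac_double = mean(.data$descent_system == "double"),
      .groups = "drop"
    ) %>%
    filter(.data$n > 0L) %>%
    mutate(structure = as.character(.data$structure))
}

#' One-parameter sensitivity sweep
#'
#' Repeats the phase tabulation at a fixed (d_c, d_m) point while varying one
#' of `N_s`, `N_f` or `mu`, to probe how group-level selection strength,
#' within-society population size and mutational fluctuation shift the
#' emergent structures.
#'
#' @param param One of `"N_s"`, `"N_f"`, `"mu"`.
#' @param values Values the parameter takes.
#' @param base A [kin_params()] object fixing everything else, including the
#'   (d_c, d_m) point.
#' @inheritParams run_phase_sweep
#' @return A `phase_sweep` object whose cells are keyed by the varied
#'   parameter (column `value`).
#' @export
sensitivity_sweep <- function(param = c("N_s", "N_f", "mu"), values, base,
                              n_trials = 20L, base_seed = 1L, theta = 1.0,
                              k_max = 8L) {
  param <- match.arg(param)
  stopifnot(inherits(base, "kin_params"), length(values) >= 1L)
  runs <- purrr::map_dfr(seq_along(values), function(i) {
    b <- base
    b[[param]] <- if (param == "mu") as.numeric(values[i]) else
      as.integer(values[i])
    purrr::map_dfr(seq_len(n_trials), function(j) {
      seed <- base_seed + (i - 1L) * n_trials + (j - 1L)
      run_one_trial(b$d_c, b$d_m, b, seed, theta, k_max) %>%
        mutate(param = param, value = values[i], .before = 1L)
    })
  })
  cells <- summarise_cells(runs, c("param", "value", "d_c", "d_m"))
  structure(list(cells = cells, runs = runs, base = base,
                 n_trials = n_trials, base_seed = base_seed),
            class = "phase_sweep")
}
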