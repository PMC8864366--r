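# Empirical estimation pipeline for SCCS-style cross-cultural tables:
# z-score the indicator variables, align their signs, average them into
# per-society cooperation/competition pressure estimates (dc_tilde, dm_tilde),
# shift the minima to zero, and rank variables by their mean absolute Spearman
# correlation with kinship-structure contrasts.

#' Default variable-to-parameter mapping
#'
#' The ten indicator variables used to estimate the cooperation pressure
#' (tributary payments or taxation, cross-cutting ties, and society-level
#' external conflict) and the competition pressure (attitudes towards
#' adultery and intra-society conflict). All default signs are +1: larger
#' values indicate a larger pressure.
#'
#' @return A tibble with columns `variable`, `target` ("d_c" or "d_m") and
#'   `sign` (+1 or -1).
#' @export
sccs_default_mapping <- function() {
  tibble::tribble(
    ~variable, ~target, ~sign,
    "tributary_payments_or_taxation", "d_c", 1,
    "violence_against_other_ethnic_groups", "d_c", 1,
    "external_warfare", "d_c", 1,
    "hostility_towards_other_ethnic_groups", "d_c", 1,
    "cross_cutting_ties", "d_c", 1,
    "conflict_within_the_society", "d_m", 1,
    "violence_within_the_society", "d_m", 1,
    "disapproval_of_rape", "d_m", 1,
    "disapproval_of_premarital_sex", "d_m", 1,
    "disapproval_of_incest", "d_m", 1
  )
}

label_cols <- c("society_id", "structure", "descent")

variable_columns <- function(table, variables = NULL) {
  if (is.null(variables)) variables <- setdiff(names(table), label_cols)
  missing_cols <- setdiff(variables, names(table))
  if (length(missing_cols)) {
    abort(paste0("variables not in table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  variables
}

#' Z-score the indicator variables of a society table
#'
#' Normalizes each variable to mean 0 and variance 1 over its non-missing
#' entries; missing cells stay missing. Variables with fewer than two distinct
#' non-missing values cannot be normalized and are dropped with a warning.
#'
#' @param table A data frame with one row per society; every column other
#'   than `society_id`, `structure`, `descent` is treated as a variable
#'   unless `variables` says otherwise.
#' @param variables Optional character vector of variable columns.
#' @return The table as a tibble with normalized variables.
#' @export
normalize_variables <- function(table, variables = NULL) {
  variables <- variable_columns(table, variables)
  out <- tibble::as_tibble(table)
  drop <- character(0)
  for (v in variables) {
    x <- out[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L) {
      drop <- c(drop, v)
      next
    }
    out[[v]] <- (x - mean(x[ok])) / sd(x[ok])
  }
  if (length(drop)) {
    warn(paste0("dropping constant variable(s): ", paste(drop, collapse = ", ")))
    out <- select(out, -all_of(drop))
  }
  out
}

#' Estimate per-society cooperation and competition pressures
#'
#' Averages the (sign-aligned, normalized) indicator variables mapped to each
#' parameter over the values available for a society, then shifts each
#' estimate so its minimum over societies is exactly 0 — the model's
#' parameters are non-negative, and only relative magnitudes are identified.
#' Societies with no available variable for a target get `NA`.
#'
#' @param table A normalized society table (see [normalize_variables()]).
#' @param mapping A mapping tibble (`variable`, `target`, `sign`); default
#'   [sccs_default_mapping()]. Only mapped variables present in the table are
#'   used.
#' @return A tibble `society_id`, `dc_tilde`, `dm_tilde` (plus `structure` /
#'   `descent` carried through when present).
#' @export
estimate_dc_dm <- function(table, mapping = sccs_default_mapping()) {
  table <- tibble::as_tibble(table)
  signed_mean <- function(target) {
    map_t <- filter(mapping, .data$target == !!target,
                    .data$variable %in% names(table))
    if (nrow(map_t) == 0L) return(rep(NA_real_, nrow(table)))
    vals <- purrr::map2(map_t$variable, map_t$sign,
                        function(v, s) s * table[[v]])
    m <- do.call(cbind, vals)
    est <- rowMeans(m, na.rm = TRUE)
    est[is.nan(est)] <- NA_real_
    est
  }
  dc <- signed_mean("d_c")
  dm <- signed_mean("d_m")
  shift0 <- function(v) if (all(is.na(v))) v else v - min(v, na.rm = TRUE)
  out <- tibble::tibble(
    society_id = table$society_id,
    dc_tilde = shift0(dc),
    dm_tilde = shift0(dm)
  )
  for (cl in intersect(c("structure", "descent"), names(table))) {
    out[[cl]] <- table[[cl]]
  }
  out
}

# Spearman rank correlation via the rank formula (ties mid-ranked),
# pairwise-complete
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(rank(x), rank(y))
}

#' Rank variables by mean absolute Spearman correlation with structure pairs
#'
#' For each unordered pair of kinship-structure classes present, restricts the
#' table to societies of those two classes, codes the pair as 0/1, computes
#' the Spearman rank correlation between the coding and each variable
#' (pairwise-complete, ties mid-ranked), then averages |rho| over pairs and
#' sorts the variables in descending order. Pairs with fewer than 3 usable
#' societies for a variable are skipped for that variable.
#'
#' @param table A (typically normalized) society table with a `structure`
#'   column.
#' @param variables Optional character vector of variable columns.
#' @param exclude Structure labels to leave out (default "excluded").
#' @return A tibble `variable`, `mean_abs_rho`, `n_pairs`, sorted descending;
#'   per-pair correlations are attached as the `pairs` attribute.
#' @export
spearman_pair_correlations <- function(table, variables = NULL,
                                       exclude = "excluded") {
  table <- tibble::as_tibble(table)
  if (!"structure" %in% names(table)) abort("table needs a `structure` column.")
  variables <- variable_columns(table, variables)
  table <- filter(table, !is.na(.data$structure),
                  !.data$structure %in% exclude)
  classes <- sort(unique(table$structure))
  if (length(classes) < 2L) abort("need at least two structure classes.")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    sub <- filter(table, .data$structure %in% pr)
    y <- as.numeric(sub$structure == pr[2L])
    purrr::map_dfr(variables, function(v) {
      tibble::tibble(class_a = pr[1L], class_b = pr[2L], variable = v,
                     rho = spearman_rho(sub[[v]], y))
    })
  })
  skipped <- sum(is.na(rows$rho))
  if (skipped > 0L) {
    warn(sprintf("%d pair-variable combinations had <3 usable societies or no variance; skipped.",
                 skipped))
  }
  ranked <- rows %>%
    group_by(.data$variable) %>%
    summarise(mean_abs_rho = mean(abs(.data$rho), na.rm = TRUE),
              n_pairs = sum(!is.na(.data$rho)), .groups = "drop") %>%
    arrange(desc(.data$mean_abs_rho))
  attr(ranked, "pairs") <- rows
  ranked
}

#' Empirical phase table of structures over estimated pressures
#'
#' Joins the per-society pressure estimates with their structure labels and
#' summarizes, per structure, the median estimated pressures and the median
#' of the ratio dm_tilde / dc_tilde — the quantity whose ordering across
#' dual organization, generalized exchange and restricted exchange mirrors
#' the theoretical phase diagram.
#'
#' @param estimates Output of [estimate_dc_dm()] (needs a `structure` column,
#'   either carried through or joined beforehand).
#' @return A list with `societies` (per-society rows, with `ratio`) and
#'   `by_structure` (per-structure medians, ordered by median ratio).
#' @export
empirical_phase_table <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  if (!"structure" %in% names(estimates)) {
    abort("estimates need a `structure` column.")
  }
  societies <- estimates %>%
    filter(!is.na(.data$dc_tilde), !is.na(.data$dm_tilde)) %>%
    mutate(ratio = .data$dm_tilde / .data$dc_tilde)
  by_structure <- societies %>%
    group_by(.data$structure) %>%
    summarise(n = n(),
              median_dc = median(.data$dc_tilde),
              median_dm = median(.data$dm_tilde),
              median_ratio = median(.data$ratio),
              .groups = "drop") %>%
    arrange(.data$median_ratio)
  list(societies = societies, by_structure = by_structure)
}
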