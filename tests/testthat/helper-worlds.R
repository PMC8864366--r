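# Hand-built worlds for driving the reference engine's phases directly.
# fams_per_soc: list of tibbles (t1, t2, p1, p2) with optional columns
# men0/men1/wom0/wom1 (unmarried counts by age) and has_repro.

mk_world <- function(params, fams_per_soc) {
  L <- params$unmarried_lifespan
  fid <- 0L
  societies <- lapply(seq_along(fams_per_soc), function(s) {
    tb <- fams_per_soc[[s]]
    fams <- lapply(seq_len(nrow(tb)), function(i) {
      fid <<- fid + 1L
      f <- list(id = fid, t1 = tb$t1[i], t2 = tb$t2[i],
                p1 = tb$p1[i], p2 = tb$p2[i],
                has_repro = isTRUE(tb$has_repro[i]),
                men = integer(L), women = integer(L))
      if (!is.null(tb[["men0"]])) f$men[1] <- tb[["men0"]][i]
      if (!is.null(tb[["men1"]]) && L >= 2) f$men[2] <- tb[["men1"]][i]
      if (!is.null(tb[["wom0"]])) f$women[1] <- tb[["wom0"]][i]
      if (!is.null(tb[["wom1"]]) && L >= 2) f$women[2] <- tb[["wom1"]][i]
      f
    })
    list(id = s, families = fams)
  })
  list(societies = societies, step = 1L, next_family_id = fid + 1L,
       next_society_id = length(fams_per_soc) + 1L,
       events = list(), summaries = list(), splits = list(),
       outcome = "running")
}

count_members <- function(world, what = "men") {
  sum(vapply(world$societies, function(s)
    sum(vapply(s$families, function(f) sum(f[[what]]), 0L)), 0L))
}
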