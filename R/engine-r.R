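# Pure-R reference engine.
#
# A straight-line transliteration of the generational life cycle:
#   reproduce -> marry -> age/cull -> split/replace.
# It is deliberately unoptimized (lists of family records) and exists as the
# readable reference implementation; run_kinship_sim(engine = "cpp") runs the
# same algorithm in compiled code and must produce bit-identical trajectories.
#
# RNG draw order (shared contract with the C++ engine; all draws come from the
# R RNG so set.seed() governs both engines):
#   Per step:
#   A. societies in roster order; families with pending reproduction in roster
#      order: M ~ Poisson(r), then F ~ Poisson(r)   (two rpois draws each).
#   B. societies in roster order; men enumerated (family roster order, then
#      age 0..L-1); one runif per man; men processed by ascending draw
#      (stable); one runif per man for the marriage offer over the
#      phase-start roster; four rnorm (t1, t2, p1, p2) only when the offer
#      lands on a family with an available woman.
#   C. ageing/culling draws nothing.
#   D. one runif per splitting society (processing order, ascending, stable);
#      per split: one runif per family (partition), one runif (which society
#      is replaced).

new_family_r <- function(id, t1, t2, p1, p2, L) {
  list(id = id, t1 = t1, t2 = t2, p1 = p1, p2 = p2,
       has_repro = FALSE, men = integer(L), women = integer(L))
}

kin_init_r <- function(params, init = NULL) {
  L <- params$unmarried_lifespan
  fid <- 0L
  societies <- vector("list", params$N_s)
  for (s in seq_len(params$N_s)) {
    fams <- vector("list", params$N_f)
    for (k in seq_len(params$N_f)) {
      fid <- fid + 1L
      if (is.null(init)) {
        fams[[k]] <- new_family_r(fid, 0, 0, 0, 0, L)
      } else {
        row <- ((k - 1L) %% nrow(init)) + 1L
        fams[[k]] <- new_family_r(fid, init[row, 1], init[row, 2],
                                  init[row, 3], init[row, 4], L)
      }
    }
    societies[[s]] <- list(id = s, families = fams)
  }
  list(societies = societies, step = 0L,
       next_family_id = fid + 1L, next_society_id = params$N_s + 1L,
       events = list(), summaries = list(), splits = list(),
       outcome = "running")
}

# interaction profile of society (list of family records); returns r vector
profile_r_engine <- function(fams, params) {
  tb <- tibble::tibble(
    t1 = vapply(fams, `[[`, 0, "t1"), t2 = vapply(fams, `[[`, 0, "t2"),
    p1 = vapply(fams, `[[`, 0, "p1"), p2 = vapply(fams, `[[`, 0, "p2")
  )
  interaction_profile(tb, params)$r
}

step_reproduce_r <- function(world, params) {
  for (s in seq_along(world$societies)) {
    fams <- world$societies[[s]]$families
    if (length(fams) == 0L) next
    pending <- which(!vapply(fams, `[[`, TRUE, "has_repro"))
    if (length(pending) == 0L) next
    r_all <- profile_r_engine(fams, params)
    for (i in pending) {
      m <- rpois(1L, r_all[i])
      f <- rpois(1L, r_all[i])
      fams[[i]]$men[1] <- fams[[i]]$men[1] + m
      fams[[i]]$women[1] <- fams[[i]]$women[1] + f
      fams[[i]]$has_repro <- TRUE
    }
    world$societies[[s]]$families <- fams
  }
  world
}

step_marriage_r <- function(world, params) {
  L <- params$unmarried_lifespan
  tau2 <- params$tau^2
  for (s in seq_along(world$societies)) {
    soc <- world$societies[[s]]
    fams <- soc$families
    if (length(fams) == 0L) next
    # enumerate man slots: family roster order, then age 0..L-1
    slot_fam <- integer(0); slot_age <- integer(0)
    for (fi in seq_along(fams)) {
      for (a in seq_len(L)) {
        nm <- fams[[fi]]$men[a]
        if (nm > 0L) {
          slot_fam <- c(slot_fam, rep(fi, nm))
          slot_age <- c(slot_age, rep(a, nm))
        }
      }
    }
    if (length(slot_fam) == 0L) next
    u <- runif(length(slot_fam))
    ord <- order(u)
    F0 <- length(fams)  # the marriage pool Phi is the phase-start roster
    for (k in ord) {
      g <- slot_fam[k]
      tg1 <- fams[[g]]$t1; tg2 <- fams[[g]]$t2
      w <- numeric(F0)
      for (j in seq_len(F0)) {
        w[j] <- exp(-((tg1 - fams[[j]]$p1)^2 + (tg2 - fams[[j]]$p2)^2) / tau2)
      }
      ssum <- sum(w)
      if (ssum <= 0) { w <- rep(1, F0); ssum <- F0 }
      v <- runif(1L) * ssum
      cum <- 0; b <- F0
      for (j in seq_len(F0)) {
        cum <- cum + w[j]
        if (cum >= v) { b <- j; break }
      }
      # the offer fails (the man stays unmarried this round) when the chosen
      # family has no unmarried woman
      if (sum(fams[[b]]$women) == 0L) next
      # consume the bride (oldest age first) and the groom
      for (a in L:1) {
        if (fams[[b]]$women[a] > 0L) {
          fams[[b]]$women[a] <- fams[[b]]$women[a] - 1L
          break
        }
      }
      fams[[g]]$men[slot_age[k]] <- fams[[g]]$men[slot_age[k]] - 1L
      child <- inherit(fams[[g]], fams[[b]], params$mu)
      cid <- world$next_family_id
      world$next_family_id <- world$next_family_id + 1L
      fams[[length(fams) + 1L]] <- new_family_r(cid, child$t1, child$t2,
                                                child$p1, child$p2, L)
      world$events[[length(world$events) + 1L]] <- list(
        step = world$step, society_id = soc$id,
        groom_family_id = fams[[g]]$id, bride_family_id = fams[[b]]$id,
        child_family_id = cid,
        g_t1 = fams[[g]]$t1, g_t2 = fams[[g]]$t2,
        g_p1 = fams[[g]]$p1, g_p2 = fams[[g]]$p2,
        b_t1 = fams[[b]]$t1, b_t2 = fams[[b]]$t2,
        b_p1 = fams[[b]]$p1, b_p2 = fams[[b]]$p2,
        c_t1 = child$t1, c_t2 = child$t2, c_p1 = child$p1, c_p2 = child$p2
      )
    }
    world$societies[[s]]$families <- fams
  }
  world
}

step_cull_r <- function(world, params) {
  L <- params$unmarried_lifespan
  for (s in seq_along(world$societies)) {
    fams <- world$societies[[s]]$families
    if (length(fams) == 0L) next
    keep <- logical(length(fams))
    for (fi in seq_along(fams)) {
      f <- fams[[fi]]
      # age: members at age L-1 (slot L) die; others move up one slot
      f$men <- c(0L, f$men[seq_len(L - 1L)])
      f$women <- c(0L, f$women[seq_len(L - 1L)])
      fams[[fi]] <- f
      keep[fi] <- (sum(f$men) + sum(f$women) > 0L) || !f$has_repro
    }
    world$societies[[s]]$families <- fams[keep]
  }
  world
}

step_split_r <- function(world, params) {
  thr <- split_threshold(params)
  sizes <- vapply(world$societies, function(s) length(s$families), 0L)
  cand <- which(sizes >= thr)
  if (length(cand) == 0L) return(world)
  u <- runif(length(cand))
  queue <- vapply(world$societies[cand[order(u)]], `[[`, 0L, "id")
  while (length(queue) > 0L) {
    sid <- queue[1L]; queue <- queue[-1L]
    pos <- which(vapply(world$societies, `[[`, 0L, "id") == sid)
    if (length(pos) == 0L) next  # already replaced by an earlier removal
    fams <- world$societies[[pos]]$families
    n <- length(fams)
    if (n < thr) next
    uf <- runif(n)
    ordf <- order(uf)
    stay <- sort(ordf[seq_len(ceiling(n / 2))])
    leave <- sort(ordf[-seq_len(ceiling(n / 2))])
    new_soc <- list(id = world$next_society_id, families = fams[leave])
    world$next_society_id <- world$next_society_id + 1L
    world$societies[[pos]]$families <- fams[stay]
    # remove one of the other societies uniformly at random; the new half
    # takes its slot, keeping the society count fixed
    others <- setdiff(seq_along(world$societies), pos)
    ridx <- others[min(floor(runif(1L) * length(others)) + 1L, length(others))]
    world$splits[[length(world$splits) + 1L]] <- list(
      step = world$step, parent_id = sid, child_id = new_soc$id,
      removed_id = world$societies[[ridx]]$id)
    world$societies[[ridx]] <- new_soc
    if (length(world$societies[[pos]]$families) >= thr) queue <- c(queue, sid)
    if (length(new_soc$families) >= thr) queue <- c(queue, new_soc$id)
  }
  world
}

summarise_step_r <- function(world) {
  fams <- unlist(lapply(world$societies, `[[`, "families"), recursive = FALSE)
  nf <- length(fams)
  pop <- if (nf) sum(vapply(fams, function(f) sum(f$men) + sum(f$women), 0L)) else 0L
  gv <- function(nm) vapply(fams, `[[`, 0, nm)
  vr <- function(x) if (length(x) >= 2L) var(x) else NA_real_
  list(step = world$step, n_families = nf,
       n_societies_alive = sum(vapply(world$societies,
                                      function(s) length(s$families) > 0L, TRUE)),
       population = pop,
       var_t1 = if (nf) vr(gv("t1")) else NA_real_,
       var_t2 = if (nf) vr(gv("t2")) else NA_real_,
       var_p1 = if (nf) vr(gv("p1")) else NA_real_,
       var_p2 = if (nf) vr(gv("p2")) else NA_real_)
}

run_engine_r <- function(params, init = NULL) {
  world <- kin_init_r(params, init)
  for (n in seq_len(params$n_steps)) {
    world$step <- n
    world <- step_reproduce_r(world, params)
    world <- step_marriage_r(world, params)
    world <- step_cull_r(world, params)
    world <- step_split_r(world, params)
    # trim the event log to the trailing window
    if (length(world$events)) {
      keep <- vapply(world$events, `[[`, 0L, "step") > n - params$event_window
      world$events <- world$events[keep]
    }
    world$summaries[[length(world$summaries) + 1L]] <- summarise_step_r(world)
    if (all(vapply(world$societies,
                   function(s) length(s$families) == 0L, TRUE))) {
      world$outcome <- "extinct"
      break
    }
  }
  if (world$outcome != "extinct") world$outcome <- "completed"
  world_to_result(world, params)
}

world_to_result <- function(world, params) {
  rows <- list()
  for (s in world$societies) {
    for (f in s$families) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        society_id = s$id, family_id = f$id,
        t1 = f$t1, t2 = f$t2, p1 = f$p1, p2 = f$p2,
        n_men = sum(f$men), n_women = sum(f$women)
      )
    }
  }
  families <- if (length(rows)) bind_rows(rows) else
    tibble::tibble(society_id = integer(), family_id = integer(),
                   t1 = double(), t2 = double(), p1 = double(), p2 = double(),
                   n_men = integer(), n_women = integer())
  events <- if (length(world$events)) bind_rows(lapply(world$events,
                                                       tibble::as_tibble)) else
    empty_events()
  summary <- if (length(world$summaries))
    bind_rows(lapply(world$summaries, tibble::as_tibble)) else
    tibble::tibble()
  splits <- if (length(world$splits))
    bind_rows(lapply(world$splits, tibble::as_tibble)) else
    tibble::tibble(step = integer(), parent_id = integer(),
                   child_id = integer(), removed_id = integer())
  new_kinship_sim(families, events, summary, world$outcome, world$step,
                  params, splits)
}

empty_events <- function() {
  tibble::tibble(step = integer(), society_id = integer(),
                 groom_family_id = integer(), bride_family_id = integer(),
                 child_family_id = integer(),
                 g_t1 = double(), g_t2 = double(), g_p1 = double(),
                 g_p2 = double(), b_t1 = double(), b_t2 = double(),
                 b_p1 = double(), b_p2 = double(), c_t1 = double(),
                 c_t2 = double(), c_p1 = double(), c_p2 = double())
}
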