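# Clan detection and kinship-structure classification.
#
# Families of a converged society form clusters ("clans") in the joint 4-D
# (t1, t2, p1, p2) space. Clusters are found by a k-sweep with multiple
# k-means restarts scored by a spherical-Gaussian BIC (the model-selection
# rule of X-means). Marriage and descent relationships between clans are then
# read off the cluster centres, and the lengths of the cycles they form (C_m,
# C_d) determine the kinship structure.

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

points_matrix <- function(points) {
  need <- c("t1", "t2", "p1", "p2")
  if (is.matrix(points)) {
    if (ncol(points) != 4L) abort("point matrix must have 4 columns.")
    colnames(points) <- need
    return(points)
  }
  if (!all(need %in% names(points))) {
    abort("`points` must have columns t1, t2, p1, p2.")
  }
  as.matrix(points[, need])
}

# Spherical-Gaussian BIC of a hard k-means partition (X-means flavour):
# smaller is better.
kmeans_bic <- function(rss, n, k, sizes, d = 4L) {
  sigma2 <- max(rss / (n * d), 1e-12)
  ll <- sum(sizes * log(sizes / n)) -
    n * d / 2 * log(2 * pi * sigma2) - rss / (2 * sigma2)
  q <- k * d + k  # centroids, mixing proportions (k - 1) and variance
  q * log(n) - 2 * ll
}

kmeans_restarts <- function(x, k, nstart) {
  ux <- unique(x)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers, iter.max = 100L)),
      error = function(e) NULL
    )
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  best
}

#' Detect clans by BIC-scored k-means
#'
#' Sweeps k = 1..`k_max` (capped at the number of distinct points), fitting
#' k-means with `nstart` random restarts in the raw 4-D (t1, t2, p1, p2)
#' space, and keeps the k minimizing a spherical-Gaussian BIC. The cloud is
#' clustered in raw units deliberately: inactive trait dimensions carry only
#' mutational drift, and rescaling them to unit variance would promote that
#' noise to the same footing as the diverged dimensions.
#'
#' @param points A data frame with columns `t1`, `t2`, `p1`, `p2` (or an n x 4
#'   matrix in that column order), one row per family.
#' @param k_max Largest number of clans considered (default 8).
#' @param nstart Random restarts per k (default 10).
#' @param seed Optional integer; when given, clustering runs on a private RNG
#'   stream and is fully deterministic without disturbing the caller's RNG.
#' @return A `clan_partition`: list with `labels` (clan index per family),
#'   `centroids` (k x 4 matrix), `k`, `sizes`, `bic` and the whole `bic_by_k`
#'   sweep.
#' @examples
#' pts <- make_clan_cloud(kind = "dual", seed = 1)$points
#' cluster_families(pts, seed = 1)$k
#' @export
cluster_families <- function(points, k_max = 8L, nstart = 10L, seed = NULL) {
  x <- points_matrix(points)
  n <- nrow(x)
  if (n == 0L) abort("no families to cluster (extinct society).")
  n_unique <- nrow(unique(x))
  kmx <- max(1L, min(as.integer(k_max), n_unique))
  with_local_seed(seed, {
    fits <- vector("list", kmx)
    bics <- rep(NA_real_, kmx)
    for (k in seq_len(kmx)) {
      if (k == 1L) {
        ctr <- matrix(colMeans(x), nrow = 1L,
                      dimnames = list(NULL, colnames(x)))
        rss <- sum(sweep(x, 2L, ctr[1L, ])^2)
        fits[[k]] <- list(cluster = rep(1L, n), centers = ctr,
                          tot.withinss = rss, size = n)
      } else {
        km <- kmeans_restarts(x, k, nstart)
        if (is.null(km)) next
        fits[[k]] <- km
      }
      bics[k] <- kmeans_bic(fits[[k]]$tot.withinss, n, k, fits[[k]]$size)
    }
    kbest <- which.min(bics)
    fit <- fits[[kbest]]
    structure(
      list(labels = as.integer(fit$cluster),
           centroids = fit$centers, k = kbest,
           sizes = as.integer(fit$size), bic = bics[kbest],
           bic_by_k = tibble::tibble(k = seq_len(kmx), bic = bics)),
      class = "clan_partition"
    )
  })
}

#' @export
print.clan_partition <- function(x, ...) {
  cat(sprintf("<clan_partition> k = %d clans over %d families (BIC %.1f)\n",
              x$k, length(x$labels), x$bic))
  invisible(x)
}

# Merge mixture components that overlap as densities: k-means happily cuts an
# elongated, drift-smeared clan into slabs, and two slabs of one clan are
# recognizable by the posterior mass they share under the spherical mixture
# implied by the fit. Components are merged greedily while the Bhattacharyya
# affinity of their responsibility vectors exceeds `kappa`; genuinely distinct
# clans (separated by several within-clan standard deviations) share
# essentially no posterior mass and survive.
merge_partition <- function(partition, x, kappa) {
  k <- partition$k
  if (k <= 1L || kappa <= 0) return(partition)
  n <- nrow(x)
  cent <- partition$centroids
  rss <- sum((x - cent[partition$labels, , drop = FALSE])^2)
  s2 <- max(rss / (n * ncol(x)), 1e-12)
  d2 <- vapply(seq_len(k), function(j)
    rowSums((x - matrix(cent[j, ], n, ncol(x), byrow = TRUE))^2), numeric(n))
  d2 <- matrix(d2, nrow = n)
  lw <- sweep(-d2 / (2 * s2), 2L, log(partition$sizes / n), "+")
  lw <- lw - apply(lw, 1L, max)
  z <- exp(lw)
  z <- z / rowSums(z)
  lab <- seq_len(k)
  repeat {
    clans <- sort(unique(lab))
    if (length(clans) <= 1L) break
    zz <- vapply(clans, function(cl)
      rowSums(z[, lab == cl, drop = FALSE]), numeric(n))
    zz <- matrix(zz, nrow = n)
    best <- NULL
    for (a in seq_along(clans)) {
      for (b in seq_len(a - 1L)) {
        ov <- sum(sqrt(zz[, a] * zz[, b])) /
          sqrt(sum(zz[, a]) * sum(zz[, b]))
        if (ov > kappa && (is.null(best) || ov > best$ov)) {
          best <- list(a = clans[a], b = clans[b], ov = ov)
        }
      }
    }
    if (is.null(best)) break
    lab[lab == best$a] <- best$b
  }
  clans <- sort(unique(lab))
  if (length(clans) == k) return(partition)
  relab <- match(lab, clans)
  labels <- relab[partition$labels]
  sizes <- tabulate(labels, length(clans))
  mcent <- t(vapply(seq_along(clans), function(cl) {
    w <- partition$sizes[relab == cl]
    colSums(cent[relab == cl, , drop = FALSE] * w) / sum(w)
  }, numeric(ncol(cent))))
  colnames(mcent) <- colnames(cent)
  structure(list(labels = labels, centroids = mcent, k = length(clans),
                 sizes = sizes, bic = partition$bic,
                 bic_by_k = partition$bic_by_k),
            class = "clan_partition")
}

nearest_centroid <- function(v, centroids) {
  d2 <- colSums((t(centroids) - v)^2)
  which.min(d2)  # ties: lowest clan index
}

#' Marriage and descent graphs between clans
#'
#' Reads the between-clan relationships off the cluster centres. The marriage
#' edge of clan X points to the clan Y whose trait centroid best matches X's
#' preference centroid (women of X marry men of Y, written X => Y). Descent is
#' traced along both parental lines: for the paternal map, the children of
#' clan A's men carry (t1, p1) of A and (t2, p2) of the clan whose women marry
#' into A; the assembled child vector is assigned to its nearest centroid.
#' The maternal map does the same for the children of each clan's women. The
#' descent cycle C_d is taken as the shorter of the two lines' cycle lengths,
#' which is what the inheriting line yields: patrilineal or matrilineal
#' systems give C_d = 1 and double-descent restricted exchange gives C_d = 2.
#'
#' @param partition A `clan_partition` from [cluster_families()].
#' @return A `clan_graphs` list: integer maps `marriage`, `descent_paternal`,
#'   `descent_maternal` (index i gives the target clan of clan i).
#' @export
build_clan_graphs <- function(partition) {
  cent <- partition$centroids
  k <- partition$k
  tmat <- cent[, c("t1", "t2"), drop = FALSE]
  pmat <- cent[, c("p1", "p2"), drop = FALSE]
  marriage <- integer(k)
  for (i in seq_len(k)) {
    d2 <- (pmat[i, 1] - tmat[, 1])^2 + (pmat[i, 2] - tmat[, 2])^2
    marriage[i] <- which.min(d2)
  }
  bride_of <- function(a) {
    w <- which(marriage == a)
    if (length(w) == 1L) return(w)
    cand <- if (length(w) > 1L) w else seq_len(k)
    d2 <- (pmat[cand, 1] - tmat[a, 1])^2 + (pmat[cand, 2] - tmat[a, 2])^2
    cand[which.min(d2)]
  }
  descent_paternal <- integer(k)
  descent_maternal <- integer(k)
  for (a in seq_len(k)) {
    w <- bride_of(a)
    child <- c(t1 = cent[a, "t1"], t2 = cent[w, "t2"],
               p1 = cent[a, "p1"], p2 = cent[w, "p2"])
    descent_paternal[a] <- nearest_centroid(child[c(1, 2, 3, 4)],
                                            cent[, c("t1", "t2", "p1", "p2"),
                                                 drop = FALSE])
  }
  for (x in seq_len(k)) {
    y <- marriage[x]
    child <- c(t1 = cent[y, "t1"], t2 = cent[x, "t2"],
               p1 = cent[y, "p1"], p2 = cent[x, "p2"])
    descent_maternal[x] <- nearest_centroid(child,
                                            cent[, c("t1", "t2", "p1", "p2"),
                                                 drop = FALSE])
  }
  structure(list(marriage = marriage,
                 descent_paternal = descent_paternal,
                 descent_maternal = descent_maternal),
            class = "clan_graphs")
}

#' Cycle length of a functional clan graph
#'
#' Every node of a total functional graph (one outgoing edge per node) leads
#' into exactly one cycle. Returns the length of that cycle; when the graph
#' holds several cycles of different lengths, returns the length of the cycle
#' carrying the most families (via `weights`) and flags the graph as
#' inconsistent. Several cycles of equal length are not inconsistent: e.g.
#' restricted exchange has two disjoint marriage 2-cycles.
#'
#' @param edge_map Integer vector; `edge_map[i]` is the successor of node i.
#' @param weights Optional per-node family counts (defaults to 1 each).
#' @return List with `length`, `inconsistent`, `n_cycles`, `cycle_lengths`.
#' @examples
#' cycle_length(c(2L, 3L, 1L))$length  # A -> B -> C -> A: 3
#' @export
cycle_length <- function(edge_map, weights = NULL) {
  k <- length(edge_map)
  stopifnot(k >= 1L, all(edge_map >= 1L), all(edge_map <= k))
  if (is.null(weights)) weights <- rep(1, k)
  # colour: 0 unvisited, else the cycle id the node leads to (negative while
  # on the current path)
  cycle_id <- integer(k)
  cycle_len <- integer(0)
  cycle_wt <- numeric(0)
  cycle_min_node <- integer(0)
  for (start in seq_len(k)) {
    if (cycle_id[start] != 0L) next
    path <- integer(0)
    v <- start
    while (cycle_id[v] == 0L) {
      cycle_id[v] <- -1L
      path <- c(path, v)
      v <- edge_map[v]
    }
    if (cycle_id[v] == -1L) {
      # new cycle: nodes from v's position in path to the end
      pos <- match(v, path)
      cyc <- path[pos:length(path)]
      cid <- length(cycle_len) + 1L
      cycle_len[cid] <- length(cyc)
      cycle_wt[cid] <- sum(weights[cyc])
      cycle_min_node[cid] <- min(cyc)
      cycle_id[cyc] <- cid
      tail_nodes <- if (pos > 1L) path[seq_len(pos - 1L)] else integer(0)
      cycle_id[tail_nodes] <- cid
    } else {
      cycle_id[path] <- cycle_id[v]
    }
  }
  lens <- unique(cycle_len)
  inconsistent <- length(lens) > 1L
  best <- order(-cycle_wt, cycle_min_node)[1L]
  list(length = cycle_len[best], inconsistent = inconsistent,
       n_cycles = length(cycle_len), cycle_lengths = cycle_len)
}

#' Classify the descent system from clan centroid spread
#'
#' A trait dimension is "significant" when the spread (range) of the clan
#' centroids along it exceeds `theta * tau`. Clans diverging along the
#' paternally inherited t1 only indicate patrilineal descent; along the
#' maternally inherited t2 only, matrilineal; along both, double descent. A
#' single undifferentiated clan is "undivided"; several clans separated in
#' neither trait dimension are "ambiguous".
#'
#' @param partition A `clan_partition`.
#' @param tau Tolerance parameter of the run that produced the points.
#' @param theta Significance threshold in units of `tau` (default 1).
#' @return One of "patrilineal", "matrilineal", "double", "undivided",
#'   "ambiguous".
#' @export
classify_descent <- function(partition, tau = 1.0, theta = 1.0) {
  cent <- partition$centroids
  if (partition$k == 1L) return("undivided")
  spread <- function(v) diff(range(v))
  sig1 <- spread(cent[, "t1"]) > theta * tau
  sig2 <- spread(cent[, "t2"]) > theta * tau
  if (sig1 && sig2) "double"
  else if (sig1) "patrilineal"
  else if (sig2) "matrilineal"
  else "ambiguous"
}

structure_from_cycles <- function(C_m, C_d, k, inconsistent) {
  if (inconsistent) return("other")
  if (C_m == 1L && C_d == 1L && k == 1L) "clan_endogamy"
  else if (C_m == 2L && C_d == 1L) "dual_organization"
  else if (C_m >= 3L && C_d == 1L) "generalized_exchange"
  else if (C_m == 2L && C_d == 2L) "restricted_exchange"
  else "other"
}

#' Classify the kinship structure of a point cloud
#'
#' Full pipeline: cluster the families of one society into clans, build the
#' between-clan marriage and descent graphs from the cluster centres, measure
#' the marriage cycle C_m and descent cycle C_d, and name the structure:
#' clan endogamy (C_m = C_d = 1, one clan), dual organization (C_m = 2,
#' C_d = 1), generalized exchange (C_m >= 3, C_d = 1), restricted exchange
#' (C_m = C_d = 2); anything else — including several endogamous clans or
#' graphs whose cycles disagree in length — is "other". The descent system
#' label (patrilineal / matrilineal / double / undivided / ambiguous) comes
#' from the centroid spread along the two trait dimensions.
#'
#' @param points A data frame of one society's families (columns t1, t2, p1,
#'   p2), e.g. [largest_society()] output, or a `kinship_sim` object (its
#'   largest society is classified).
#' @param tau,theta See [classify_descent()].
#' @param k_max,nstart,seed Passed to [cluster_families()].
#' @param merge_kappa Posterior-overlap threshold above which clusters are
#'   merged into one clan before the graphs are read (default 0.1; 0 disables
#'   merging). Clusters carved out of one drift-elongated clan share posterior
#'   mass under the fitted mixture and are re-united; well-separated clans are
#'   untouched.
#' @return A `kinship_structure` object; see [glance.kinship_structure()].
#' @examples
#' cloud <- make_clan_cloud(kind = "generalized", k = 3, seed = 2)
#' glance(classify_kinship(cloud$points, seed = 1))
#' @export
classify_kinship <- function(points, tau = 1.0, theta = 1.0, k_max = 8L,
                             nstart = 10L, seed = NULL, merge_kappa = 0.1) {
  if (inherits(points, "kinship_sim")) points <- largest_society(points)
  if (is.null(dim(points)) || nrow(points) == 0L) {
    return(structure(list(structure = "extinct", descent_system = "extinct",
                          C_m = NA_integer_, C_d = NA_integer_,
                          k = 0L, inconsistent = FALSE, partition = NULL,
                          graphs = NULL),
                     class = "kinship_structure"))
  }
  partition <- cluster_families(points, k_max = k_max, nstart = nstart,
                                seed = seed)
  partition <- merge_partition(partition, points_matrix(points), merge_kappa)
  graphs <- build_clan_graphs(partition)
  wts <- partition$sizes
  cm <- cycle_length(graphs$marriage, wts)
  cdp <- cycle_length(graphs$descent_paternal, wts)
  cdm <- cycle_length(graphs$descent_maternal, wts)
  # descent runs along the line that actually confers clan membership: the
  # shorter of the paternal and maternal cycles
  if (cdp$length <= cdm$length) {
    C_d <- cdp$length; d_inc <- cdp$inconsistent
  } else {
    C_d <- cdm$length; d_inc <- cdm$inconsistent
  }
  inconsistent <- cm$inconsistent || d_inc
  structure(
    list(structure = structure_from_cycles(cm$length, C_d, partition$k,
                                           inconsistent),
         descent_system = classify_descent(partition, tau, theta),
         C_m = cm$length, C_d = C_d, k = partition$k,
         inconsistent = inconsistent,
         partition = partition, graphs = graphs),
    class = "kinship_structure"
  )
}

#' @export
print.kinship_structure <- function(x, ...) {
  cat(sprintf("<kinship_structure> %s (C_m = %s, C_d = %s, %d clans), %s descent\n",
              x$structure, x$C_m, x$C_d, x$k, x$descent_system))
  invisible(x)
}

#' Structure classification summaries
#'
#' `glance()` returns the one-row classification (structure, descent system,
#' C_m, C_d, number of clans, inconsistency flag); `tidy()` returns the
#' per-clan table of centroids and sizes with marriage/descent targets.
#'
#' @param x A `kinship_structure` object.
#' @param ... Unused.
#' @export
glance.kinship_structure <- function(x, ...) {
  tibble::tibble(structure = x$structure, descent_system = x$descent_system,
                 C_m = x$C_m, C_d = x$C_d, n_clans = x$k,
                 inconsistent = x$inconsistent)
}

#' @rdname glance.kinship_structure
#' @export
tidy.kinship_structure <- function(x, ...) {
  if (is.null(x$partition)) return(tibble::tibble())
  cent <- x$partition$centroids
  tibble::tibble(
    clan = seq_len(x$k),
    n_families = x$partition$sizes,
    t1 = cent[, "t1"], t2 = cent[, "t2"],
    p1 = cent[, "p1"], p2 = cent[, "p2"],
    marries_into = x$graphs$marriage,
    paternal_child_clan = x$graphs$descent_paternal,
    maternal_child_clan = x$graphs$descent_maternal
  )
}

#' Cross-check clan graphs against the logged marriages
#'
#' Instead of reading relationships off cluster centres, tallies the actual
#' marriage events of the trailing generations: for each bride clan, the modal
#' groom clan defines the marriage edge; the modal groom-clan to child-clan
#' (and bride-clan to child-clan) transitions define the two descent maps.
#' Clans with no logged events get an `NA` edge, and callers should fall back
#' to the centroid-based graphs for them.
#'
#' @param events An event tibble as returned in `run_kinship_sim()$events`
#'   (needs the coordinate columns g_*, b_*, c_*).
#' @param partition A `clan_partition` for the same society.
#' @return A `clan_graphs` list (entries may be `NA` for clans without
#'   events).
#' @export
trace_event_graphs <- function(events, partition) {
  if (nrow(events) == 0L) abort("empty event log.")
  cent <- partition$centroids
  assign_clan <- function(prefix) {
    m <- as.matrix(events[, paste0(prefix, c("_t1", "_t2", "_p1", "_p2"))])
    apply(m, 1L, nearest_centroid, centroids = cent)
  }
  g_clan <- assign_clan("g")
  b_clan <- assign_clan("b")
  c_clan <- assign_clan("c")
  k <- partition$k
  modal_map <- function(from, to) {
    out <- rep(NA_integer_, k)
    for (i in seq_len(k)) {
      tt <- to[from == i]
      if (length(tt) == 0L) next
      tab <- tabulate(tt, nbins = k)
      out[i] <- which.max(tab)
    }
    out
  }
  structure(list(marriage = modal_map(b_clan, g_clan),
                 descent_paternal = modal_map(g_clan, c_clan),
                 descent_maternal = modal_map(b_clan, c_clan)),
            class = "clan_graphs")
}

#' Three-panel clan cloud plot
#'
#' The conventional inspection views of a society's final state: (t1, p1),
#' (t2, p2) and (t1, t2) scatter plots coloured by clan.
#'
#' @param points Data frame with t1, t2, p1, p2.
#' @param partition Optional `clan_partition` supplying clan colours.
#' @return A ggplot object (facetted panels).
#' @export
plot_clan_cloud <- function(points, partition = NULL) {
  pts <- tibble::as_tibble(points_matrix(points))
  pts$clan <- if (is.null(partition)) factor(1L) else factor(partition$labels)
  long <- bind_rows(
    tibble::tibble(x = pts$t1, y = pts$p1, clan = pts$clan,
                   panel = "t1 vs p1"),
    tibble::tibble(x = pts$t2, y = pts$p2, clan = pts$clan,
                   panel = "t2 vs p2"),
    tibble::tibble(x = pts$t1, y = pts$t2, clan = pts$clan,
                   panel = "t1 vs t2")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$clan)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}
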