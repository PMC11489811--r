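# Connected components of suprathreshold (site, time) points under the
# relation: spatial neighbour at the same time sample OR same site at an
# adjacent (+/- 1) time sample. Fmat/mask are sites x time matrices.
cluster_from_mask <- function(Fmat, mask, adjacency, effect = NA_character_) {
  S <- nrow(Fmat); Tn <- ncol(Fmat)
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  rk <- integer(S * Tn); rk[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  site_of <- (idx - 1L) %% S + 1L
  for (k in seq_along(idx)) {
    p <- idx[k]
    s <- site_of[k]
    tnext <- p + S
    if (tnext <= S * Tn && rk[tnext] > 0L) union(k, rk[tnext])
    for (s2 in adjacency[[s]]) if (s2 > s) {
      p2 <- p + (s2 - s)
      if (rk[p2] > 0L) union(k, rk[p2])
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  comp <- split(seq_along(idx), roots)
  lapply(unname(comp), function(members) {
    pts <- idx[members]
    s <- (pts - 1L) %% S + 1L
    tt <- (pts - 1L) %/% S + 1L
    list(effect = effect,
         members = cbind(site = s, time = tt),
         points = pts,
         sites = sort(unique(s)),
         time_range = range(tt),
         mass = sum(Fmat[pts]),
         p = NA_real_)
  })
}

#' Form spatiotemporal clusters from a pointwise F map
#'
#' Thresholds the map at pointwise `p < point_alpha` and groups the
#' suprathreshold points into connected components under the adjacency
#' relation (spatial neighbour at the same time, or same site at an
#' adjacent time sample). The cluster statistic is the mass (sum of F over
#' members).
#'
#' @param fmap One effect entry of a [pointwise_rm_anova()] result (a list
#'   with `F` and `p` sites x time matrices).
#' @param point_alpha Pointwise significance criterion (default 0.05).
#' @param adjacency Spatial adjacency list from [site_adjacency()].
#' @return List of clusters; each has `members` (site/time index matrix),
#'   `sites`, `time_range`, `mass` and a `p` slot (`NA` until filled by
#'   [permutation_null()]).
#' @export
form_clusters <- function(fmap, point_alpha = 0.05, adjacency) {
  stopifnot(is.matrix(fmap$F))
  cluster_from_mask(fmap$F, fmap$p < point_alpha, adjacency,
                    effect = fmap$effect %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge adjacent clusters of the same effect
#'
#' Clusters whose member sets are spatiotemporally adjacent (sharing a
#' point, spatial neighbours at the same time, or the same site at
#' consecutive time samples) are unioned; masses add and the merged
#' cluster's p-value is the minimum of its parts. Idempotent and
#' order-independent.
#'
#' @param clusters List of clusters of one effect (see [form_clusters()]).
#' @param adjacency Spatial adjacency list.
#' @param n_sites Number of sites of the grid the clusters live on.
#' @return List of merged clusters.
#' @export
merge_clusters <- function(clusters, adjacency, n_sites) {
  n <- length(clusters)
  if (n <= 1) return(clusters)
  if (length(unique(vapply(clusters, `[[`, character(1), "effect"))) > 1)
    stop("merge_clusters: clusters must share one effect", call. = FALSE)
  S <- n_sites
  # neighbourhood key set of a cluster: its points plus all their neighbours
  nbr_keys <- function(cl) {
    pts <- cl$points
    s <- (pts - 1L) %% S + 1L
    ks <- c(pts, pts + S, pts - S,
            unlist(lapply(seq_along(pts),
                          function(k) pts[k] + (adjacency[[s[k]]] - s[k]))))
    unique(ks)
  }
  keys <- lapply(clusters, nbr_keys)
  pts <- lapply(clusters, `[[`, "points")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (any(pts[[j]] %in% keys[[i]])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unname(split(seq_len(n), roots)), function(grp) {
    if (length(grp) == 1) return(clusters[[grp]])
    mem <- do.call(rbind, lapply(clusters[grp], `[[`, "members"))
    allpts <- unlist(lapply(clusters[grp], `[[`, "points"))
    list(effect = clusters[[grp[1]]]$effect,
         members = mem,
         points = allpts,
         sites = sort(unique(mem[, "site"])),
         time_range = range(mem[, "time"]),
         mass = sum(vapply(clusters[grp], `[[`, numeric(1), "mass")),
         p = suppressWarnings(min(vapply(clusters[grp], `[[`, numeric(1), "p"))))
  })
}

#' Mean source activity inside a cluster, per subject and condition
#'
#' @param activity Array `subjects x tasks x pictures x sites x time`.
#' @param cluster A cluster from [form_clusters()].
#' @return Array `subjects x tasks x pictures` of means over the cluster's
#'   (site, time) members.
#' @export
extract_cluster_mean <- function(activity, cluster) {
  d <- dim(activity)
  stopifnot(length(d) == 5)
  if (max(cluster$members[, "site"]) > d[4] ||
      max(cluster$members[, "time"]) > d[5])
    stop("cluster members outside data bounds", call. = FALSE)
  flat <- array(activity, c(d[1] * d[2] * d[3], d[4] * d[5]))
  pts <- (cluster$members[, "time"] - 1L) * d[4] + cluster$members[, "site"]
  array(rowMeans(flat[, pts, drop = FALSE]), d[1:3])
}

#' Tabulate clusters as a report data frame
#'
#' @param clusters List of clusters (with permutation p-values filled in).
#' @param time_ms Optional time axis (ms) to express the cluster extent in
#'   milliseconds.
#' @return Data frame: effect, n_points, n_sites, time window, mass, p.
#' @export
cluster_table <- function(clusters, time_ms = NULL) {
  if (length(clusters) == 0)
    return(data.frame(effect = character(), n_points = integer(),
                      n_sites = integer(), t_start = numeric(),
                      t_end = numeric(), mass = numeric(), p = numeric()))
  tv <- function(i) if (is.null(time_ms)) i else time_ms[i]
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    effect = cl$effect, n_points = nrow(cl$members),
    n_sites = length(cl$sites),
    t_start = tv(cl$time_range[1]), t_end = tv(cl$time_range[2]),
    mass = cl$mass, p = cl$p, stringsAsFactors = FALSE)))
}
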