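#' Geographic anchor point of a reference candidate
#'
#' A candidate's location is the midpoint of their parents' birth places,
#' provided the parents were born within `max_parent_sep_km` of each other.
#' Individuals with missing parental coordinates or parents further apart
#' are ineligible (returns `NA`s, not an error).
#'
#' @param metadata data.frame with columns `parent1_x`, `parent1_y`,
#'   `parent2_x`, `parent2_y` (km, planar grid).
#' @param max_parent_sep_km maximum parental separation (default 80).
#' @return data.frame with columns `id`, `x`, `y`, `eligible`.
#' @export
candidate_locations <- function(metadata, max_parent_sep_km = 80) {
  need <- c("parent1_x", "parent1_y", "parent2_x", "parent2_y")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks parental coordinates: ", paste(miss, collapse = ", "))
  sep <- sqrt((metadata$parent1_x - metadata$parent2_x)^2 +
              (metadata$parent1_y - metadata$parent2_y)^2)
  eligible <- !is.na(sep) & sep <= max_parent_sep_km
  data.frame(
    id = metadata$id,
    x = ifelse(eligible, (metadata$parent1_x + metadata$parent2_x) / 2, NA_real_),
    y = ifelse(eligible, (metadata$parent1_y + metadata$parent2_y) / 2, NA_real_),
    eligible = eligible,
    stringsAsFactors = FALSE
  )
}

#' Count neighbors within a radius
#'
#' For each point, the number of *other* points at Euclidean distance at
#' most `radius_km` (a distance exactly equal to the radius counts).
#'
#' @param points numeric matrix or data.frame with two coordinate columns.
#' @param radius_km positive radius in km.
#' @return integer vector of neighbor counts.
#' @export
count_neighbors <- function(points, radius_km) {
  stopifnot(radius_km > 0)
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  d <- as.matrix(stats::dist(xy))
  as.integer(colSums(d <= radius_km) - 1L)
}

#' Two-phase spatial thinning of over-dense point clouds
#'
#' Phase 1: while any retained point has more than `local_max` neighbors
#' within `local_radius`, one point is removed, chosen uniformly at random
#' among all points currently over the local cap; counts are recomputed
#' over the retained points after every removal. Phase 2: while any
#' retained point has more than `global_max` neighbors within
#' `global_radius`, one point is removed uniformly among those that attain
#' the maximal local-neighbor count within the over-cap set. On exit every
#' retained point satisfies both caps.
#'
#' @param points matrix/data.frame of planar coordinates (km).
#' @param local_radius,local_max local cap (defaults 5 km, 15 neighbors).
#' @param global_radius,global_max global cap (defaults 30 km, 40 neighbors).
#' @param seed integer seed making the random removals reproducible.
#' @return list with `kept` (integer indices into `points`) and
#'   `exclusions` (data.frame: index, phase, local and global counts at
#'   removal, removal order).
#' @export
spatial_thin <- function(points, local_radius = 5, local_max = 15,
                         global_radius = 30, global_max = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  if (!all(is.finite(xy))) stop("non-finite coordinates")
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  loc_adj <- d <= local_radius
  glob_adj <- d <= global_radius
  diag(loc_adj) <- diag(glob_adj) <- FALSE
  alive <- rep(TRUE, n)
  loc_cnt <- as.integer(rowSums(loc_adj))
  glob_cnt <- as.integer(rowSums(glob_adj))
  excl <- list()

  drop_point <- function(v, phase) {
    excl[[length(excl) + 1L]] <<- data.frame(
      index = v, phase = phase,
      local_count = loc_cnt[v], global_count = glob_cnt[v],
      order = length(excl) + 1L
    )
    alive[v] <<- FALSE
    nb_l <- which(alive & loc_adj[v, ])
    nb_g <- which(alive & glob_adj[v, ])
    loc_cnt[nb_l] <<- loc_cnt[nb_l] - 1L
    glob_cnt[nb_g] <<- glob_cnt[nb_g] - 1L
  }

  repeat {
    over <- which(alive & loc_cnt > local_max)
    if (!length(over)) break
    v <- if (length(over) == 1L) over else sample(over, 1L)
    drop_point(v, "local")
  }
  repeat {
    over <- which(alive & glob_cnt > global_max)
    if (!length(over)) break
    cand <- over[loc_cnt[over] == max(loc_cnt[over])]
    v <- if (length(cand) == 1L) cand else sample(cand, 1L)
    drop_point(v, "global")
  }

  list(
    kept = which(alive),
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(index = integer(0), phase = character(0),
                 local_count = integer(0), global_count = integer(0),
                 order = integer(0))
  )
}

#' Flag geographic outliers within labelled groups
#'
#' Flags group members strictly farther than `max_dist_km` from their
#' group's coordinate-wise median. Groups with fewer than 3 members are
#' skipped with a warning.
#'
#' @param points matrix/data.frame of planar coordinates (km), rownames or
#'   an `id` column used as identifiers.
#' @param group_labels vector of group labels, one per point.
#' @param max_dist_km flagging distance.
#' @return character vector of flagged ids (row names / indices).
#' @export
flag_geographic_outliers <- function(points, group_labels, max_dist_km) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  ids <- rownames(xy)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(xy)))
  flagged <- character(0)
  for (g in unique(as.character(group_labels))) {
    sel <- which(as.character(group_labels) == g)
    if (length(sel) < 3L) {
      warning("group '", g, "' has fewer than 3 members; skipped")
      next
    }
    med <- apply(xy[sel, , drop = FALSE], 2, stats::median)
    dd <- sqrt((xy[sel, 1] - med[1])^2 + (xy[sel, 2] - med[2])^2)
    flagged <- c(flagged, ids[sel[dd > max_dist_km]])
  }
  flagged
}
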