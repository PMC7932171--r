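#' Distance-weighted municipal ancestry profiles
#'
#' The profile of municipality m is the weighted average of all individual
#' profiles, each weighted by the inverse squared Euclidean distance
#' between the individual's birth place and the municipality centre:
#' `A_m = (1 / r_Tot) * sum_i a_i / r_im^2`, `r_Tot = sum_i 1 / r_im^2`.
#' Distances are floored at `min_dist_km` so nearby individuals cannot
#' dominate with unbounded weights. Every individual contributes to every
#' municipality; `max_radius_km` optionally restricts contributions to a
#' cutoff radius (a documented deviation from the all-individuals sum).
#'
#' @param profiles matrix of individual profiles (rows = ids).
#' @param individual_xy matrix/data.frame of planar coordinates (km), rows
#'   parallel to `profiles`.
#' @param municipality_centers data.frame with columns `municipality_id`,
#'   `x`, `y`.
#' @param min_dist_km distance floor (default 5).
#' @param max_radius_km optional cutoff radius; `Inf` (default) sums over
#'   all individuals.
#' @return data.frame with columns `municipality_id`, `group`,
#'   `proportion`, `r_tot`, `n_contributing`.
#' @export
municipal_average <- function(profiles, individual_xy, municipality_centers,
                              min_dist_km = 5, max_radius_km = Inf) {
  if (nrow(profiles) < 1L) stop("no individuals with profiles")
  xy <- as.matrix(individual_xy)[, 1:2, drop = FALSE]
  stopifnot(nrow(xy) == nrow(profiles))
  out <- list()
  for (k in seq_len(nrow(municipality_centers))) {
    mc <- municipality_centers[k, ]
    d <- sqrt((xy[, 1] - mc$x)^2 + (xy[, 2] - mc$y)^2)
    keep <- d <= max_radius_km
    if (!any(keep)) next
    r <- pmax(d[keep], min_dist_km)
    w <- 1 / r^2
    r_tot <- sum(w)
    A <- colSums(profiles[keep, , drop = FALSE] * w) / r_tot
    out[[length(out) + 1L]] <- data.frame(
      municipality_id = mc$municipality_id,
      group = colnames(profiles),
      proportion = as.numeric(A),
      r_tot = r_tot,
      n_contributing = sum(keep),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
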