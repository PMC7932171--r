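#' Copyvector matrix for a set of recipients
#'
#' Paints each recipient against the donor set (leaving the recipient out
#' when it is itself a donor) and aggregates the per-donor expected copying
#' amounts to a fixed basis of donor populations. The basis is shared by
#' all recipients and by the surrogate model built from them.
#'
#' @param panel a `haplotype_panel`.
#' @param ids recipient individual ids.
#' @param donor_ids donor individual ids.
#' @param basis named vector mapping each donor id to its basis-population
#'   label (e.g. a [cut_population_tree()] result at the basis level).
#' @param use `"chunks"` (default) or `"lengths"`.
#' @param switch_rate,mutation_prob copying-model parameters.
#' @return numeric matrix, rows = recipients, columns = basis populations.
#' @export
copyvector_matrix <- function(panel, ids, donor_ids, basis,
                              use = c("chunks", "lengths"),
                              switch_rate = 3720.27, mutation_prob = 0.00014) {
  use <- match.arg(use)
  if (anyNA(basis[donor_ids])) stop("basis does not cover all donors")
  pops <- unique(unname(basis[donor_ids]))
  X <- matrix(0, length(ids), length(pops), dimnames = list(ids, pops))
  for (id in ids) {
    dons <- setdiff(donor_ids, id)
    cv <- paint_recipient(as_recipient(panel, id), panel, donor_ids = dons,
                          switch_rate = switch_rate, mutation_prob = mutation_prob,
                          donor_units = basis)
    v <- if (use == "chunks") cv$chunk_counts else cv$lengths
    X[id, names(v)] <- v
  }
  X
}

#' Build a surrogate model of group mean copyvectors
#'
#' Averages the individual copyvectors (already aggregated to the shared
#' basis) within each reference group.
#'
#' @param X copyvector matrix from [copyvector_matrix()].
#' @param groups named list: group name -> member ids (all present in `X`).
#' @return object of class `surrogate_model`: list with `V` (groups x
#'   basis matrix of group means), `n` (group sizes).
#' @export
group_copyvectors <- function(X, groups) {
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0L]
  if (length(empty)) stop("empty group: ", paste(empty, collapse = ", "))
  V <- t(vapply(groups, function(ids) {
    miss <- setdiff(ids, rownames(X))
    if (length(miss)) stop("members lacking copyvectors: ", paste(miss, collapse = ", "))
    colMeans(X[ids, , drop = FALSE])
  }, numeric(ncol(X))))
  colnames(V) <- colnames(X)
  if (any(V < 0)) stop("negative group copyvector entries")
  structure(list(V = V, n = vapply(groups, length, integer(1))),
            class = "surrogate_model")
}

# exact simplex-constrained least squares by active-set enumeration:
# minimize ||t - V' w||^2 over w >= 0, sum(w) = 1. For each support set,
# the equality-constrained problem is solved through its KKT system and
# kept if feasible; the best feasible solution is the global optimum.
simplex_ls <- function(target, V, tol = 1e-9) {
  G <- nrow(V)
  if (G > 20L) stop("simplex_ls supports at most 20 groups")
  best <- NULL
  best_obj <- Inf
  A_full <- V %*% t(V)
  b_full <- as.vector(V %*% target)
  for (mask in 1:(2^G - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(G) - 1L)) > 0L)
    k <- length(S)
    KKT <- rbind(cbind(2 * A_full[S, S, drop = FALSE], rep(1, k)),
                 c(rep(1, k), 0))
    rhs <- c(2 * b_full[S], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w_s <- sol[seq_len(k)]
    if (any(w_s < -tol)) next
    w_s[w_s < 0] <- 0
    w_s <- w_s / sum(w_s)
    w <- numeric(G)
    w[S] <- w_s
    obj <- sum((target - as.vector(t(V) %*% w))^2)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- w
    }
  }
  stats::setNames(best, rownames(V))
}

# Metropolis-within-Gibbs posterior mean under a multinomial likelihood of
# basis chunk counts with a symmetric Dirichlet prior on the weights
simplex_mcmc <- function(target, V, burn_in = 500L, n_iter = 2000L,
                         thin = 50L, alpha = 1, step = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- nrow(V)
  Q <- V / pmax(rowSums(V), .Machine$double.eps)  # per-group basis composition
  tgt <- pmax(target, 0)
  loglik <- function(w) {
    mix <- as.vector(t(Q) %*% w)
    sum(tgt * log(pmax(mix, 1e-300))) + sum((alpha - 1) * log(pmax(w, 1e-300)))
  }
  w <- rep(1 / G, G)
  ll <- loglik(w)
  draws <- list()
  for (it in seq_len(burn_in + n_iter)) {
    ij <- sample.int(G, 2L)
    delta <- stats::runif(1, -step, step)
    w2 <- w
    w2[ij[1]] <- w[ij[1]] + delta
    w2[ij[2]] <- w[ij[2]] - delta
    if (all(w2 >= 0)) {
      ll2 <- loglik(w2)
      if (log(stats::runif(1)) < ll2 - ll) {
        w <- w2; ll <- ll2
      }
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      draws[[length(draws) + 1L]] <- w
    }
  }
  out <- colMeans(do.call(rbind, draws))
  stats::setNames(out / sum(out), rownames(V))
}

#' Estimate an ancestry profile from a copyvector
#'
#' Expresses a target copyvector as a mixture of the reference-group mean
#' copyvectors. The default `"simplex-ls"` method minimizes the squared
#' error subject to non-negativity and sum-to-one, solved exactly; the
#' `"mcmc"` method returns the posterior mean of the mixture weights under
#' a multinomial likelihood of the basis chunk counts with a symmetric
#' Dirichlet prior.
#'
#' @param target numeric copyvector over the model's basis (named), or a
#'   row of a [copyvector_matrix()].
#' @param model a `surrogate_model`.
#' @param method `"simplex-ls"` (default) or `"mcmc"`.
#' @param mcmc_params list overriding `burn_in`, `n_iter`, `thin`, `alpha`,
#'   `step`, `seed` for the MCMC method.
#' @return named numeric profile on the simplex.
#' @export
estimate_profile <- function(target, model, method = c("simplex-ls", "mcmc"),
                             mcmc_params = list()) {
  method <- match.arg(method)
  V <- model$V
  if (!is.null(names(target))) target <- target[colnames(V)]
  if (anyNA(target)) stop("target copyvector does not match model basis")
  spread <- max(apply(V, 2, function(col) diff(range(col))))
  if (spread < 1e-12) {
    warning("degenerate model: all group vectors identical; returning uniform profile")
    return(stats::setNames(rep(1 / nrow(V), nrow(V)), rownames(V)))
  }
  if (method == "simplex-ls") {
    simplex_ls(as.numeric(target), V)
  } else {
    do.call(simplex_mcmc, c(list(target = as.numeric(target), V = V), mcmc_params))
  }
}

#' Estimate profiles for many targets against full reference groups
#'
#' @param X copyvector matrix (targets in rows).
#' @param groups named list of reference-group member ids.
#' @param ... passed to [estimate_profile()].
#' @return matrix of profiles, rows = targets, columns = groups.
#' @export
estimate_profiles <- function(X, groups, ...) {
  model <- group_copyvectors(X, groups)
  t(apply(X, 1, estimate_profile, model = model, ...))
}

#' Leave-one-out ancestry profiles for reference members
#'
#' For each member of each reference group, the group's mean copyvector is
#' recomputed without that member before its profile is estimated; the
#' other groups keep their full means. Every group needs at least 2
#' members.
#'
#' @param X copyvector matrix containing all reference members.
#' @param groups named list of reference-group member ids.
#' @param ... passed to [estimate_profile()].
#' @return matrix of profiles, rows = reference members, columns = groups.
#' @export
leave_one_out_profiles <- function(X, groups, ...) {
  singles <- names(groups)[vapply(groups, length, integer(1)) < 2L]
  if (length(singles)) stop("singleton group: ", paste(singles, collapse = ", "))
  model <- group_copyvectors(X, groups)
  members <- unlist(groups, use.names = FALSE)
  P <- matrix(0, length(members), length(groups),
              dimnames = list(members, names(groups)))
  for (g in names(groups)) {
    n_g <- length(groups[[g]])
    for (m in groups[[g]]) {
      V <- model$V
      V[g, ] <- (n_g * V[g, ] - X[m, ]) / (n_g - 1)
      loo_model <- structure(list(V = V, n = model$n), class = "surrogate_model")
      P[m, ] <- estimate_profile(X[m, ], loo_model, ...)
    }
  }
  P
}

#' Shrink small ancestry proportions to zero
#'
#' Entries strictly below `threshold` are set to zero and the remainder is
#' renormalized to sum to one. If every entry is below the threshold, the
#' single largest entry is kept at 1.
#'
#' @param profile named numeric simplex vector.
#' @param threshold shrink threshold (default 0.05).
#' @return shrunk profile on the simplex.
#' @export
shrink_profile <- function(profile, threshold = 0.05) {
  if (any(profile < 0)) stop("negative profile entry")
  out <- profile
  out[out < threshold] <- 0
  s <- sum(out)
  if (s == 0) {
    out[] <- 0
    out[which.max(profile)] <- 1
    return(out)
  }
  out / s
}

#' Identity proportions of candidate populations
#'
#' For each population, the mean of its assigned members' own-population
#' ancestry proportion. Low values mark populations indistinguishable from
#' the others.
#'
#' @param profiles matrix of profiles (rows = individuals, columns =
#'   populations).
#' @param population_assignment named vector id -> population.
#' @return named numeric vector in `[0, 1]`, one entry per population with
#'   assigned members.
#' @export
identity_proportions <- function(profiles, population_assignment) {
  pops <- intersect(unique(unname(population_assignment)), colnames(profiles))
  out <- stats::setNames(numeric(length(pops)), pops)
  for (p in pops) {
    members <- names(population_assignment)[population_assignment == p]
    miss <- setdiff(members, rownames(profiles))
    if (length(miss)) stop("member lacking a profile: ", paste(miss, collapse = ", "))
    out[p] <- mean(profiles[members, p])
  }
  out
}

#' Select statistically separable reference groups
#'
#' The iterative identity-proportion procedure: cut the population tree at
#' `K_start`; estimate leave-one-out ancestry profiles of all candidates
#' against the current populations; compute identity proportions; drop
#' every population below `pop_identity_min` and re-estimate, until no
#' population is dropped. Then drop individual members whose own-group
#' leave-one-out proportion is below `member_min`, and finally (when
#' coordinates are supplied) drop geographic outliers by group-median
#' distance. Individual copyvectors are painted once against the full
#' candidate set and reused across iterations.
#'
#' @param tree a `population_tree` over the candidates.
#' @param panel a `haplotype_panel` containing the candidates.
#' @param K_start number of populations at the starting cut.
#' @param pop_identity_min minimum population identity proportion
#'   (default 0.5).
#' @param member_min minimum member self-ancestry; conventionally 0.95 for
#'   a 2-group reference set and 0.70 for finer sets (default 0.7).
#' @param basis_level tree-cut level defining the copyvector basis
#'   (default 20, truncated to the number of candidates).
#' @param coords optional matrix of planar coordinates (rownames = ids)
#'   enabling the geographic-outlier step.
#' @param outlier_max_dist_km distance threshold for the outlier step
#'   (default 150).
#' @param switch_rate,mutation_prob copying-model parameters.
#' @param estimation_method passed to [estimate_profile()].
#' @param X optional precomputed candidate copyvector matrix over the basis
#'   (rows = candidates); when supplied the painting step is skipped and
#'   `panel` may be `NULL`.
#' @return object of class `reference_set`: list with `groups` (named list
#'   of member ids), `identity` (final identity proportions), `profiles`
#'   (final leave-one-out profiles of the kept members), `basis`
#'   (donor id -> basis population), `X` (candidate copyvector matrix) and
#'   `audit` (per-iteration record of identities and exclusions).
#' @export
select_reference_groups <- function(tree, panel, K_start,
                                    pop_identity_min = 0.5, member_min = 0.7,
                                    basis_level = 20, coords = NULL,
                                    outlier_max_dist_km = 150,
                                    switch_rate = 3720.27,
                                    mutation_prob = 0.00014,
                                    estimation_method = "simplex-ls",
                                    X = NULL) {
  candidates <- tree$ids
  basis_level <- min(basis_level, length(candidates))
  basis <- cut_population_tree(tree, basis_level)
  assignment <- cut_population_tree(tree, K_start)
  if (is.null(X)) {
    X <- copyvector_matrix(panel, candidates, candidates, basis,
                           switch_rate = switch_rate, mutation_prob = mutation_prob)
  } else {
    miss <- setdiff(candidates, rownames(X))
    if (length(miss)) stop("X lacks candidates: ", paste(miss, collapse = ", "))
  }

  active_pops <- unique(unname(assignment))
  audit <- list()
  iter <- 0L
  profiles <- NULL
  repeat {
    iter <- iter + 1L
    members <- names(assignment)[assignment %in% active_pops]
    groups <- split(members, factor(unname(assignment[members]), levels = active_pops))
    small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
    if (length(small)) {
      active_pops <- setdiff(active_pops, small)
      audit[[length(audit) + 1L]] <- list(
        step = "population-exclusion", K = length(active_pops) + length(small),
        identity = NULL, dropped = small, reason = "fewer than 2 members")
      if (!length(active_pops)) stop("no separable populations at K_start")
      next
    }
    profiles <- leave_one_out_profiles(X[members, , drop = FALSE], groups,
                                       method = estimation_method)
    idp <- identity_proportions(profiles, assignment[members])
    low <- names(idp)[idp < pop_identity_min]
    audit[[length(audit) + 1L]] <- list(
      step = "population-exclusion", K = length(active_pops),
      identity = as.list(idp), dropped = low,
      reason = if (length(low)) "identity below threshold" else "none")
    if (!length(low)) break
    active_pops <- setdiff(active_pops, low)
    if (!length(active_pops)) stop("no separable populations at K_start")
    if (iter > K_start) stop("identity-proportion loop failed to terminate")
  }

  members <- names(assignment)[assignment %in% active_pops]
  self_prop <- profiles[cbind(members, unname(assignment[members]))]
  names(self_prop) <- members
  low_members <- members[self_prop < member_min]
  members <- setdiff(members, low_members)
  audit[[length(audit) + 1L]] <- list(
    step = "member-exclusion", threshold = member_min, dropped = low_members)

  outliers <- character(0)
  if (!is.null(coords)) {
    outliers <- flag_geographic_outliers(coords[members, , drop = FALSE],
                                         unname(assignment[members]),
                                         outlier_max_dist_km)
    members <- setdiff(members, outliers)
  }
  audit[[length(audit) + 1L]] <- list(
    step = "geographic-outliers", max_dist_km = outlier_max_dist_km,
    dropped = outliers)

  groups <- split(members, factor(unname(assignment[members]), levels = active_pops))
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0L]
  groups[empty] <- NULL
  if (!length(groups)) stop("no separable populations at K_start")
  final_profiles <- leave_one_out_profiles(X[members, , drop = FALSE], groups,
                                           method = estimation_method)
  final_identity <- identity_proportions(final_profiles, assignment[members])

  structure(list(
    groups = groups, identity = final_identity, profiles = final_profiles,
    assignment = assignment, basis = basis, X = X, audit = audit,
    params = list(K_start = K_start, pop_identity_min = pop_identity_min,
                  member_min = member_min, basis_level = basis_level,
                  outlier_max_dist_km = outlier_max_dist_km)
  ), class = "reference_set")
}

#' Replay a reference-selection audit trail
#'
#' Reconstructs the final groups of a [select_reference_groups()] result by
#' applying the recorded exclusions to the recorded starting assignment,
#' without re-estimating anything.
#'
#' @param refset a `reference_set`.
#' @return named list of member ids per group.
#' @export
replay_reference_audit <- function(refset) {
  assignment <- refset$assignment
  active <- unique(unname(assignment))
  members <- names(assignment)
  for (entry in refset$audit) {
    if (entry$step == "population-exclusion") {
      active <- setdiff(active, entry$dropped)
    } else {
      members <- setdiff(members, entry$dropped)
    }
  }
  members <- members[assignment[members] %in% active]
  out <- split(members, factor(unname(assignment[members]), levels = active))
  out[vapply(out, length, integer(1)) > 0L]
}
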