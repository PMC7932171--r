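#' @name painting
#' @title Haplotype-copying painter
#' @description
#' A Li-Stephens-style copying model: each recipient haplotype is modelled
#' as a mosaic of the donor haplotypes. The hidden state at a site is the
#' donor haplotype being copied; between adjacent sites the chain stays put
#' with probability `exp(-n d / H)` (`d` the inter-site distance in cM,
#' `n` the switch rate, `H` the number of donor haplotypes) and otherwise
#' switches to a uniformly chosen donor haplotype; the emission matches the
#' donor allele with probability `1 - M` and mismatches with probability
#' `M`. Forward-backward posteriors give, per donor unit, the expected
#' number of copied chunks (maximal same-unit runs) and the expected
#' copied length in cM. The model runs with fixed parameters (no EM
#' re-estimation) and a uniform donor prior, which keeps it exactly
#' checkable against brute-force path enumeration.
NULL

# scaled forward-backward for one recipient haplotype on one chromosome.
# r: recipient alleles (length L); D: donor haplotype matrix (H x L);
# cm: genetic positions; unit_of: integer unit index per donor haplotype.
# returns per-unit expected chunk counts and copied lengths.
paint_haplotype <- function(r, D, cm, switch_rate, mutation_prob, unit_of, n_units) {
  H <- nrow(D)
  L <- ncol(D)
  M <- mutation_prob
  # emissions L x H
  E <- t(ifelse(D == rep(r, each = H), 1 - M, M))
  E[is.na(E)] <- 1  # missing allele: uninformative
  d <- if (L > 1L) diff(cm) else numeric(0)
  stay <- exp(-switch_rate * d / H)

  Ahat <- matrix(0, L, H)
  cs <- numeric(L)
  a <- E[1L, ] / H
  cs[1L] <- sum(a)
  Ahat[1L, ] <- a / cs[1L]
  if (L > 1L) {
    for (t in 2:L) {
      pred <- stay[t - 1L] * Ahat[t - 1L, ] + (1 - stay[t - 1L]) / H
      a <- E[t, ] * pred
      cs[t] <- sum(a)
      Ahat[t, ] <- a / cs[t]
    }
  }
  if (any(!is.finite(Ahat))) stop("NaN in forward pass")

  Bhat <- matrix(1, L, H)
  if (L > 1L) {
    for (t in (L - 1L):1L) {
      u <- E[t + 1L, ] * Bhat[t + 1L, ]
      Bhat[t, ] <- (stay[t] * u + (1 - stay[t]) * sum(u) / H) / cs[t + 1L]
    }
  }

  Z <- matrix(0, H, n_units)
  Z[cbind(seq_len(H), unit_of)] <- 1
  Gamma_u <- (Ahat * Bhat) %*% Z          # L x U posteriors per unit
  w <- site_cm_weights(cm)
  lengths_u <- colSums(Gamma_u * w)

  # expected chunks per unit: P(start in u) + sum_t P(s_t in u, s_{t-1} not in u);
  # a switch-in always goes through the uniform term of the transition, so the
  # joint reduces to (1-stay)/H * (1 - alpha mass in u) * (emission*beta mass in u) / c_t
  chunks_u <- Gamma_u[1L, ]
  if (L > 1L) {
    EB_u <- (E * Bhat) %*% Z
    A_u <- Ahat %*% Z
    coef <- (1 - stay) / (H * cs[2:L])
    add <- (coef * EB_u[2:L, , drop = FALSE]) * (1 - A_u[1:(L - 1L), , drop = FALSE])
    chunks_u <- chunks_u + colSums(add)
  }
  list(chunks = chunks_u, lengths = lengths_u)
}

#' Paint a recipient against a donor panel
#'
#' Runs the copying model for both recipient haplotypes over all
#' chromosomes and sums the expected chunk counts and copied lengths per
#' donor unit (by default, per donor individual).
#'
#' @param recipient per-chromosome list, each element with `cm` and
#'   `haplotypes` (2 x L matrix) — the shape returned by
#'   [simulate_descendant()]; or an individual id present in `donors_panel`
#'   via [paint_panel_individual()].
#' @param donors_panel a `haplotype_panel` of donor individuals.
#' @param donor_ids ids of the donors to use (default all in panel).
#' @param switch_rate copying switch rate (default 3720.27).
#' @param mutation_prob per-site copying error probability (default 0.00014).
#' @param donor_units optional named vector mapping donor id to unit label;
#'   default one unit per donor individual.
#' @return object of class `copy_vector`: list with `chunk_counts` and
#'   `lengths` (named per unit), `n_chrom`, and `donor_units`.
#' @export
paint_recipient <- function(recipient, donors_panel, donor_ids = NULL,
                            switch_rate = 3720.27, mutation_prob = 0.00014,
                            donor_units = NULL) {
  if (is.null(donor_ids)) donor_ids <- donors_panel$individual_ids
  if (!length(donor_ids)) stop("donor panel empty")
  if (is.null(donor_units)) donor_units <- stats::setNames(donor_ids, donor_ids)
  units <- unique(unname(donor_units[donor_ids]))
  n_units <- length(units)
  idx <- match(donor_ids, donors_panel$individual_ids)
  if (anyNA(idx)) stop("unknown donor ids")
  hap_rows_all <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  unit_of <- match(rep(unname(donor_units[donor_ids]), each = 2L), units)

  chunk_counts <- stats::setNames(numeric(n_units), units)
  lengths <- stats::setNames(numeric(n_units), units)
  for (nm in names(donors_panel$chromosomes)) {
    ch <- donors_panel$chromosomes[[nm]]
    D <- ch$haplotypes[hap_rows_all, , drop = FALSE]
    rec <- recipient[[nm]]
    if (is.null(rec)) stop("recipient lacks chromosome ", nm)
    for (hap in 1:2) {
      res <- paint_haplotype(rec$haplotypes[hap, ], D, ch$cm,
                             switch_rate, mutation_prob, unit_of, n_units)
      chunk_counts <- chunk_counts + res$chunks
      lengths <- lengths + res$lengths
    }
  }
  structure(list(chunk_counts = chunk_counts, lengths = lengths,
                 n_chrom = length(donors_panel$chromosomes),
                 donor_units = donor_units),
            class = "copy_vector")
}

#' Extract an individual from a panel in recipient shape
#'
#' @param panel a `haplotype_panel`.
#' @param id individual id.
#' @return per-chromosome list with `cm` and `haplotypes` (2 x L).
#' @export
as_recipient <- function(panel, id) {
  rows <- hap_rows(panel, id)
  lapply(panel$chromosomes, function(ch) {
    list(cm = ch$cm, haplotypes = ch$haplotypes[rows, , drop = FALSE])
  })
}

#' Paint a panel member against the other members (leave-self-out)
#'
#' @param panel a `haplotype_panel`.
#' @param id recipient individual id (excluded from the donors).
#' @param donor_ids donor ids (default: all others).
#' @param ... passed to [paint_recipient()].
#' @return a `copy_vector`.
#' @export
paint_panel_individual <- function(panel, id, donor_ids = NULL, ...) {
  if (is.null(donor_ids)) donor_ids <- setdiff(panel$individual_ids, id)
  if (id %in% donor_ids) stop("recipient must not be among donors")
  paint_recipient(as_recipient(panel, id), panel, donor_ids = donor_ids, ...)
}

#' Coancestry matrix of a candidate set
#'
#' Paints every candidate against all other candidates (leave-self-out)
#' and collects the expected chunk counts into a square matrix with
#' recipients as rows, donors as columns, and a zero diagonal.
#'
#' @param panel a `haplotype_panel`.
#' @param candidate_ids ids of the candidates (at least 3).
#' @param switch_rate,mutation_prob copying-model parameters.
#' @return matrix of expected chunk counts with id dimnames.
#' @export
coancestry <- function(panel, candidate_ids = NULL,
                       switch_rate = 3720.27, mutation_prob = 0.00014) {
  if (is.null(candidate_ids)) candidate_ids <- panel$individual_ids
  n <- length(candidate_ids)
  if (n < 3L) stop("need at least 3 candidates")
  M <- matrix(0, n, n, dimnames = list(candidate_ids, candidate_ids))
  for (i in seq_len(n)) {
    id <- candidate_ids[i]
    cv <- paint_panel_individual(panel, id, donor_ids = setdiff(candidate_ids, id),
                                 switch_rate = switch_rate,
                                 mutation_prob = mutation_prob)
    M[i, names(cv$chunk_counts)] <- cv$chunk_counts
  }
  M
}

#' Build a population tree from a coancestry matrix
#'
#' Agglomerative (Ward) clustering on the Euclidean distances between
#' row-normalized coancestry profiles. The merge tree can be cut at any
#' level K to yield K nested populations.
#'
#' @param coancestry_matrix square matrix from [coancestry()].
#' @return object of class `population_tree` wrapping the `hclust` merge
#'   tree and the individual ids.
#' @export
build_population_tree <- function(coancestry_matrix) {
  if (nrow(coancestry_matrix) < 4L) stop("need a matrix over at least 4 individuals")
  if (any(!is.finite(coancestry_matrix))) stop("non-finite coancestry entries")
  prof <- coancestry_matrix / pmax(rowSums(coancestry_matrix), .Machine$double.eps)
  hc <- stats::hclust(stats::dist(prof), method = "ward.D2")
  structure(list(hclust = hc, ids = rownames(coancestry_matrix)),
            class = "population_tree")
}

#' Cut a population tree into K populations
#'
#' @param tree a `population_tree`.
#' @param K number of populations (1 to number of individuals).
#' @return named character vector of population labels (`"P1"`...`"PK"`,
#'   numbered in order of first appearance), names = individual ids.
#' @export
cut_population_tree <- function(tree, K) {
  stopifnot(K >= 1L, K <= length(tree$ids))
  memb <- stats::cutree(tree$hclust, k = K)
  lab <- paste0("P", match(memb, unique(memb)))
  stats::setNames(lab, tree$ids)
}

#' Write a population tree as Newick
#'
#' @param tree a `population_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  hc <- tree$hclust
  rec <- function(i) {
    if (i < 0) return(gsub("[,():;]", "_", hc$labels[-i]))
    kids <- hc$merge[i, ]
    sprintf("(%s,%s):%g", rec(kids[1]), rec(kids[2]), hc$height[i])
  }
  writeLines(paste0(rec(nrow(hc$merge)), ";"), path)
  invisible(path)
}
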