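#' Sample a crossover mosaic over one chromosome
#'
#' Chooses the starting parental haplotype with probability 1/2 and places a
#' crossover between adjacent loci with the Haldane (no-interference)
#' probability `r = (1 - exp(-2 d)) / 2`, `d` the inter-locus map distance
#' in Morgans. Returns, per locus, which of the two parental haplotypes the
#' gamete copies (1 or 2).
#'
#' @param cm genetic positions of the loci (cM, non-decreasing).
#' @return integer vector in `{1, 2}`, one element per locus.
#' @keywords internal
sample_crossover_sources <- function(cm) {
  L <- length(cm)
  if (L == 0L) return(integer(0))
  d <- diff(cm) / 100  # Morgans
  if (any(d < 0)) stop("negative map distance")
  r <- (1 - exp(-2 * d)) / 2
  start <- sample.int(2L, 1L)
  if (L == 1L) return(start)
  flips <- stats::runif(L - 1L) < r
  src <- cumsum(c(start - 1L, flips)) %% 2L + 1L
  as.integer(src)
}

#' Sample a gamete from a pair of phased haplotypes
#'
#' Per chromosome, applies a Haldane crossover process along the genetic
#' map and copies alleles alternately from the two parental haplotypes.
#'
#' @param parent list per chromosome, each element a list with `cm`
#'   (genetic positions) and `haps` (2 x L matrix of the parent's phased
#'   alleles, or any payload to recombine).
#' @return list per chromosome of gamete vectors (one row drawn from the
#'   mosaic of the two parental rows).
#' @export
sample_gamete <- function(parent) {
  lapply(parent, function(ch) {
    src <- sample_crossover_sources(ch$cm)
    out <- ch$haps[1L, ]
    take2 <- src == 2L
    out[take2] <- ch$haps[2L, take2]
    out
  })
}

# per-site cM weights (half-intervals, summing to the chromosome span)
site_cm_weights <- function(cm) {
  L <- length(cm)
  if (L == 0L) return(numeric(0))
  if (L == 1L) return(0)
  d <- diff(cm)
  c(d[1] / 2, (d[-(L - 1L)] + d[-1L]) / 2, d[L - 1L] / 2)
}

#' Build a pedigree specification
#'
#' @param ancestor_ids ids of the `2^G` ancestors, eldest generation first,
#'   in slot order (slots `2i - 1` and `2i` are the parents of internal
#'   node `i` of the next generation).
#' @return object of class `pedigree` with fields `G` and `ancestor_ids`.
#' @export
pedigree <- function(ancestor_ids) {
  n <- length(ancestor_ids)
  G <- as.integer(round(log2(n)))
  if (n < 2L || 2^G != n) stop("ancestor count must be a power of two >= 2")
  if (anyDuplicated(ancestor_ids)) stop("reused ancestor within one pedigree")
  structure(list(G = G, ancestor_ids = as.character(ancestor_ids)),
            class = "pedigree")
}

#' Simulate a descendant from a pedigree of ancestors
#'
#' Starting from the eldest generation, simulates the meioses down the full
#' binary pedigree and returns the generation-0 diploid together with each
#' ancestor's realized, cM-weighted fraction of the target genome. Segment
#' bookkeeping is done by recombining an ancestor-label payload alongside
#' the alleles with identical crossover patterns.
#'
#' @param ped a [pedigree()].
#' @param ancestor_panel a `haplotype_panel` containing all ancestors.
#' @param seed optional integer seed for reproducibility.
#' @return list with `chromosomes` (per-chromosome list of `cm` and a
#'   2 x L haplotype matrix), `truth_fractions` (named numeric summing to 1),
#'   and `ancestor_labels` (per-chromosome 2 x L matrix of ancestor slots).
#' @export
simulate_descendant <- function(ped, ancestor_panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  miss <- setdiff(ped$ancestor_ids, ancestor_panel$individual_ids)
  if (length(miss)) stop("ancestors absent from panel: ", paste(miss, collapse = ", "))
  chrom_names <- names(ancestor_panel$chromosomes)

  # an "individual" in flight: per chromosome, alleles (2 x L) + labels (2 x L)
  make_ancestor <- function(slot, id) {
    rows <- hap_rows(ancestor_panel, id)
    lapply(ancestor_panel$chromosomes, function(ch) {
      list(cm = ch$cm,
           alleles = ch$haplotypes[rows, , drop = FALSE],
           labels = matrix(slot, nrow = 2L, ncol = length(ch$cm)))
    })
  }
  gen <- Map(make_ancestor, seq_along(ped$ancestor_ids), ped$ancestor_ids)

  mate <- function(p1, p2) {
    out <- vector("list", length(p1))
    names(out) <- names(p1)
    for (nm in names(p1)) {
      src1 <- sample_crossover_sources(p1[[nm]]$cm)
      src2 <- sample_crossover_sources(p2[[nm]]$cm)
      pick <- function(mat, src) {
        v <- mat[1L, ]
        v[src == 2L] <- mat[2L, src == 2L]
        v
      }
      out[[nm]] <- list(
        cm = p1[[nm]]$cm,
        alleles = rbind(pick(p1[[nm]]$alleles, src1), pick(p2[[nm]]$alleles, src2)),
        labels = rbind(pick(p1[[nm]]$labels, src1), pick(p2[[nm]]$labels, src2))
      )
    }
    out
  }

  while (length(gen) > 1L) {
    gen <- lapply(seq_len(length(gen) / 2L), function(i) {
      mate(gen[[2L * i - 1L]], gen[[2L * i]])
    })
  }
  target <- gen[[1L]]

  w_total <- 0
  frac <- stats::setNames(numeric(length(ped$ancestor_ids)), ped$ancestor_ids)
  for (nm in chrom_names) {
    w <- site_cm_weights(target[[nm]]$cm)
    w_total <- w_total + 2 * sum(w)
    for (hap in 1:2) {
      tab <- tapply(w, target[[nm]]$labels[hap, ], sum)
      frac[ped$ancestor_ids[as.integer(names(tab))]] <-
        frac[ped$ancestor_ids[as.integer(names(tab))]] + tab
    }
  }
  if (w_total > 0) frac <- frac / w_total else frac[] <- 1 / length(frac)

  list(
    chromosomes = lapply(target, function(ch) list(cm = ch$cm, haplotypes = ch$alleles)),
    truth_fractions = frac,
    ancestor_labels = lapply(target, function(ch) ch$labels)
  )
}

#' Run an All-/Almost- identifiability scenario
#'
#' For each pedigree depth `G` in `G_range`, draws `2^G` ancestors without
#' replacement from the majority pool (all of them, for an "All-" scenario)
#' or `2^G - 1` from the majority pool and one from the minority pool
#' ("Almost-"), simulates the descendant, and estimates its ancestry
#' profile with the supplied estimator. Ancestors are drawn without
#' replacement within a replicate and may recur across replicates.
#'
#' @param major_pool,minor_pool character vectors of ancestor ids; pass
#'   `NULL` for `minor_pool` to run an All- scenario.
#' @param ancestor_panel a `haplotype_panel` containing the pools.
#' @param estimator function taking the `simulate_descendant()` result and
#'   returning a named simplex profile.
#' @param n_replicates replicates per G (default 20).
#' @param G_range pedigree depths (default `1:5`).
#' @param seed integer seed.
#' @return data.frame with one row per replicate x G x reference group:
#'   columns `G`, `replicate`, `group`, `proportion`, `truth_minor`
#'   (realized genomic fraction of the minority ancestor; 0 for All-).
#' @export
run_scenario <- function(major_pool, minor_pool = NULL, ancestor_panel,
                         estimator, n_replicates = 20L, G_range = 1:5,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (G in G_range) {
    n_anc <- 2^G
    n_major <- if (is.null(minor_pool)) n_anc else n_anc - 1L
    if (length(major_pool) < n_major) {
      stop("ancestor pool exhausted: majority pool at G=", G)
    }
    if (!is.null(minor_pool) && length(minor_pool) < 1L) {
      stop("ancestor pool exhausted: minority pool")
    }
    for (rep_i in seq_len(n_replicates)) {
      anc <- sample(major_pool, n_major)
      minor_id <- NULL
      if (!is.null(minor_pool)) {
        minor_id <- sample(minor_pool, 1L)
        slot <- sample.int(n_anc, 1L)
        anc <- append(anc, minor_id, after = slot - 1L)
      }
      sim <- simulate_descendant(pedigree(anc), ancestor_panel)
      prof <- estimator(sim)
      truth_minor <- if (is.null(minor_id)) 0 else unname(sim$truth_fractions[minor_id])
      rows[[length(rows) + 1L]] <- data.frame(
        G = G, replicate = rep_i, group = names(prof),
        proportion = as.numeric(prof), truth_minor = truth_minor,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Classify replicates as single-origin via the second-largest threshold
#'
#' The decision threshold for "all ancestors from X" is the second-largest
#' value of the X ancestry component among the All-X replicates (the 95%
#' quantile for 20 replicates). Almost-X replicates whose component exceeds
#' the threshold are misassigned as single-origin; All-X replicates at or
#' below it fail to be recognized as single-origin.
#'
#' @param all_values component values among All-X replicates (length >= 2).
#' @param almost_values component values among Almost-X replicates.
#' @return list with `threshold`, `misassigned_almost`, `unrecognized_all`.
#' @export
classify_single_origin <- function(all_values, almost_values) {
  if (length(all_values) < 2L) stop("need at least 2 All- replicates")
  threshold <- sort(all_values, decreasing = TRUE)[2L]
  list(
    threshold = threshold,
    misassigned_almost = sum(almost_values > threshold),
    unrecognized_all = sum(all_values <= threshold)
  )
}

#' Select ancestor candidates from a PC embedding
#'
#' Trims each candidate group in a 2-D principal-component embedding, either
#' by keeping the fraction of the group most extreme toward its pole on
#' axis 1 (`"pc1-tail"`) or by fitting a bivariate normal per group and
#' keeping members inside the highest-50%-density ellipse (`"density-50"`,
#' Mahalanobis radius at the chi-square(2) median).
#'
#' @param pc_coords numeric matrix (n x 2) with rownames = individual ids.
#' @param groups named character/factor vector of group labels (names = ids).
#' @param mode `"pc1-tail"` or `"density-50"`.
#' @param keep_frac fraction kept in `"pc1-tail"` mode (default 0.8).
#' @param poles named numeric (+1/-1 per group) for `"pc1-tail"`: -1 keeps
#'   the smallest axis-1 coordinates, +1 the largest.
#' @return named list of kept id vectors, one element per group.
#' @export
select_ancestor_candidates <- function(pc_coords, groups,
                                       mode = c("pc1-tail", "density-50"),
                                       keep_frac = 0.8, poles = NULL) {
  mode <- match.arg(mode)
  ids <- rownames(pc_coords)
  stopifnot(!is.null(ids), length(groups) == nrow(pc_coords))
  if (is.null(names(groups))) names(groups) <- ids
  out <- list()
  for (g in unique(as.character(groups))) {
    gid <- ids[as.character(groups[ids]) == g]
    if (length(gid) < 5L) stop("group '", g, "' has fewer than 5 members")
    xy <- pc_coords[gid, , drop = FALSE]
    if (mode == "pc1-tail") {
      pole <- if (is.null(poles)) -1 else poles[[g]]
      k <- floor(keep_frac * length(gid))
      ord <- order(pole * xy[, 1], decreasing = TRUE)
      out[[g]] <- gid[sort(ord[seq_len(k)])]
    } else {
      mu <- colMeans(xy)
      S <- stats::cov(xy)
      d2 <- stats::mahalanobis(xy, mu, S)
      out[[g]] <- gid[d2 <= stats::qchisq(0.5, df = 2)]
    }
  }
  out
}
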