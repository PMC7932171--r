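#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` holds phased 0/1 haplotypes for a set of diploid
#' individuals, organised per chromosome. Each chromosome carries its
#' physical positions (bp, strictly increasing) and genetic positions (cM,
#' non-decreasing); the haplotype matrix has two rows per individual, in
#' individual order (rows `2i - 1` and `2i` are the two haplotypes of
#' individual `i`).
#'
#' @param chromosomes named list; each element a list with components
#'   `positions` (integer bp), `cm` (numeric cM) and `haplotypes`
#'   (matrix of 0/1, optionally `NA` for missing, `2 * n_ind` rows).
#' @param individual_ids character vector of individual identifiers.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(chromosomes, individual_ids) {
  stopifnot(is.list(chromosomes), length(chromosomes) >= 1L)
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids")
  n_hap <- 2L * length(individual_ids)
  for (nm in names(chromosomes)) {
    ch <- chromosomes[[nm]]
    if (!all(c("positions", "cm", "haplotypes") %in% names(ch))) {
      stop("chromosome '", nm, "' lacks positions/cm/haplotypes")
    }
    if (nrow(ch$haplotypes) != n_hap) {
      stop("chromosome '", nm, "': haplotype rows != 2 x individuals")
    }
    L <- length(ch$positions)
    if (ncol(ch$haplotypes) != L || length(ch$cm) != L) {
      stop("chromosome '", nm, "': positions/cm/haplotype columns disagree")
    }
    if (L > 1L && any(diff(ch$positions) <= 0)) {
      stop("chromosome '", nm, "': physical positions not strictly increasing")
    }
    if (L > 1L && any(diff(ch$cm) < 0)) {
      stop("chromosome '", nm, "': cM positions decreasing")
    }
    vals <- ch$haplotypes[!is.na(ch$haplotypes)]
    if (length(vals) && !all(vals %in% c(0L, 1L))) {
      stop("chromosome '", nm, "': alleles must be 0/1 (NA for missing)")
    }
  }
  structure(
    list(chromosomes = chromosomes, individual_ids = individual_ids),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d individuals, %d chromosomes, %d variants\n",
    n_individuals(x), length(x$chromosomes), n_variants(x)
  ))
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel a `haplotype_panel`.
#' @return integer count.
#' @export
n_individuals <- function(panel) length(panel$individual_ids)

#' Total number of variants across chromosomes
#' @param panel a `haplotype_panel`.
#' @return integer count.
#' @export
n_variants <- function(panel) {
  sum(vapply(panel$chromosomes, function(ch) length(ch$positions), integer(1)))
}

#' Subset a panel to a set of individuals
#'
#' @param panel a `haplotype_panel`.
#' @param ids character vector of individual ids to keep (order respected).
#' @return a `haplotype_panel` with only the requested individuals.
#' @export
subset_individuals <- function(panel, ids) {
  ids <- as.character(ids)
  idx <- match(ids, panel$individual_ids)
  if (anyNA(idx)) stop("unknown individual ids: ", paste(ids[is.na(idx)], collapse = ", "))
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  chroms <- lapply(panel$chromosomes, function(ch) {
    ch$haplotypes <- ch$haplotypes[rows, , drop = FALSE]
    ch
  })
  haplotype_panel(chroms, ids)
}

#' Subset a panel to a set of variants
#'
#' @param panel a `haplotype_panel`.
#' @param keep named list (by chromosome) of logical or integer column
#'   selectors; chromosomes absent from `keep` are retained unchanged.
#' @return a `haplotype_panel`.
#' @export
subset_variants <- function(panel, keep) {
  chroms <- panel$chromosomes
  for (nm in names(keep)) {
    sel <- keep[[nm]]
    ch <- chroms[[nm]]
    ch$positions <- ch$positions[sel]
    ch$cm <- ch$cm[sel]
    ch$haplotypes <- ch$haplotypes[, sel, drop = FALSE]
    chroms[[nm]] <- ch
  }
  # drop chromosomes left without variants
  chroms <- Filter(function(ch) length(ch$positions) > 0L, chroms)
  if (!length(chroms)) stop("no variants left after subsetting")
  haplotype_panel(chroms, panel$individual_ids)
}

#' Bind two panels over the same variants (append individuals)
#'
#' @param a,b `haplotype_panel` objects with identical chromosomes,
#'   positions and cM coordinates.
#' @return a `haplotype_panel` containing the individuals of `a` then `b`.
#' @export
bind_individuals <- function(a, b) {
  stopifnot(identical(names(a$chromosomes), names(b$chromosomes)))
  chroms <- a$chromosomes
  for (nm in names(chroms)) {
    if (!identical(a$chromosomes[[nm]]$positions, b$chromosomes[[nm]]$positions)) {
      stop("panels disagree on positions for chromosome ", nm)
    }
    chroms[[nm]]$haplotypes <- rbind(
      a$chromosomes[[nm]]$haplotypes,
      b$chromosomes[[nm]]$haplotypes
    )
  }
  haplotype_panel(chroms, c(a$individual_ids, b$individual_ids))
}

# rows of the haplotype matrix belonging to one individual
hap_rows <- function(panel, id) {
  i <- match(id, panel$individual_ids)
  if (is.na(i)) stop("unknown individual id: ", id)
  c(2L * i - 1L, 2L * i)
}

# diploid genotype dosage matrix (individuals x variants) for one chromosome
chrom_dosage <- function(ch) {
  H <- ch$haplotypes
  idx1 <- seq(1L, nrow(H), by = 2L)
  H[idx1, , drop = FALSE] + H[idx1 + 1L, , drop = FALSE]
}
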