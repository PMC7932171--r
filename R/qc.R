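#' Exact test for Hardy-Weinberg equilibrium
#'
#' Levene-Haldane exact test: the p-value is the total probability, under
#' the distribution of the heterozygote count conditional on the observed
#' allele counts, of all outcomes no more probable than the observed one.
#' Computed by full enumeration in log space, so the significance threshold
#' is well defined even at small sample sizes.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return the exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(1)
  nA <- 2L * n_aa + n_ab
  nB <- 2L * n_bb + n_ab
  hs <- seq(nA %% 2L, min(nA, nB), by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((nB - hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# per-variant genotype summaries for one chromosome: returns list of
# matrices (variants x {n_aa, n_ab, n_bb, n_miss}) using allele-1 counts
chrom_geno_counts <- function(ch) {
  dos <- chrom_dosage(ch)           # NA where either haplotype missing
  n_ind <- nrow(dos)
  miss <- colSums(is.na(dos))
  n0 <- colSums(dos == 0L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  cbind(n0 = n0, n1 = n1, n2 = n2, n_miss = miss, n_ind = n_ind)
}

new_qc_report <- function(kind, counts, thresholds, n_input, n_retained) {
  stopifnot(n_input == n_retained + sum(unlist(counts)))
  structure(
    list(kind = kind, counts = counts, thresholds = thresholds,
         n_input = n_input, n_retained = n_retained),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report (%s): %d in, %d retained\n", x$kind, x$n_input, x$n_retained))
  for (nm in names(x$counts)) cat(sprintf("  removed_%s: %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Variant-level quality control
#'
#' Removes variants with minor allele frequency below `maf_min`, exact-test
#' Hardy-Weinberg p-value below `hwe_alpha`, or genotype missingness above
#' `miss_max`. Filters are applied in that order and each removed variant is
#' counted once, at the first filter it fails.
#'
#' @param panel a `haplotype_panel`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param hwe_alpha minimum HWE exact p-value (default 1e-6).
#' @param miss_max maximum per-variant genotype missingness (default 0.01).
#' @return list with components `panel` (filtered) and `report` (`qc_report`).
#' @export
variant_qc <- function(panel, maf_min = 0.05, hwe_alpha = 1e-6, miss_max = 0.01) {
  if (n_variants(panel) == 0L) stop("empty panel")
  rm_maf <- rm_hwe <- rm_miss <- 0L
  keep <- list()
  for (nm in names(panel$chromosomes)) {
    gc <- chrom_geno_counts(panel$chromosomes[[nm]])
    n_obs <- gc[, "n0"] + gc[, "n1"] + gc[, "n2"]
    p1 <- (2 * gc[, "n2"] + gc[, "n1"]) / (2 * pmax(n_obs, 1L))
    maf <- pmin(p1, 1 - p1)
    fail_maf <- maf < maf_min | n_obs == 0L
    hwe_p <- vapply(seq_len(nrow(gc)), function(j) {
      if (fail_maf[j]) return(NA_real_)
      hwe_exact_test(gc[j, "n0"], gc[j, "n1"], gc[j, "n2"])
    }, numeric(1))
    fail_hwe <- !fail_maf & !is.na(hwe_p) & hwe_p < hwe_alpha
    missr <- gc[, "n_miss"] / gc[, "n_ind"]
    fail_miss <- !fail_maf & !fail_hwe & missr > miss_max
    rm_maf <- rm_maf + sum(fail_maf)
    rm_hwe <- rm_hwe + sum(fail_hwe)
    rm_miss <- rm_miss + sum(fail_miss)
    keep[[nm]] <- !(fail_maf | fail_hwe | fail_miss)
  }
  n_in <- n_variants(panel)
  if (all(!unlist(keep))) stop("no variants survive QC")
  out <- subset_variants(panel, keep)
  report <- new_qc_report(
    "variant",
    list(maf = rm_maf, hwe = rm_hwe, missing = rm_miss),
    list(maf_min = maf_min, hwe_alpha = hwe_alpha, miss_max = miss_max),
    n_in, n_variants(out)
  )
  list(panel = out, report = report)
}

#' Method-of-moments inbreeding coefficient per individual
#'
#' `F = (O_hom - E_hom) / (n_sites - E_hom)` where `O_hom` is the observed
#' homozygous-site count and `E_hom` the expectation under Hardy-Weinberg
#' proportions at the sample allele frequencies, both over the sites where
#' the individual is genotyped.
#'
#' @param panel a `haplotype_panel`.
#' @return named numeric vector of F values, one per individual.
#' @export
inbreeding_f <- function(panel) {
  n_ind <- n_individuals(panel)
  O <- E <- L <- numeric(n_ind)
  for (nm in names(panel$chromosomes)) {
    dos <- chrom_dosage(panel$chromosomes[[nm]])
    n_obs <- colSums(!is.na(dos))
    p <- colSums(dos, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
    e_hom_site <- 1 - 2 * p * (1 - p)
    obs <- !is.na(dos)
    O <- O + rowSums(dos == 0L | dos == 2L, na.rm = TRUE)
    E <- E + as.vector(obs %*% e_hom_site)
    L <- L + rowSums(obs)
  }
  f <- (O - E) / (L - E)
  names(f) <- panel$individual_ids
  f
}

#' Sample-level quality control
#'
#' Removes individuals whose method-of-moments inbreeding coefficient lies
#' outside `het_f_bounds` or whose genotype missingness exceeds `miss_max`.
#'
#' @param panel a `haplotype_panel` with at least 2 samples.
#' @param het_f_bounds inclusive bounds on F (default `c(-0.04, 0.04)`).
#' @param miss_max maximum per-sample genotype missingness (default 0.005).
#' @return list with components `panel` and `report`.
#' @export
sample_qc <- function(panel, het_f_bounds = c(-0.04, 0.04), miss_max = 0.005) {
  if (n_individuals(panel) < 2L) stop("sample_qc needs at least 2 samples")
  f <- inbreeding_f(panel)
  miss_n <- tot_n <- numeric(n_individuals(panel))
  for (nm in names(panel$chromosomes)) {
    dos <- chrom_dosage(panel$chromosomes[[nm]])
    miss_n <- miss_n + rowSums(is.na(dos))
    tot_n <- tot_n + ncol(dos)
  }
  missr <- miss_n / tot_n
  fail_het <- f < het_f_bounds[1] | f > het_f_bounds[2]
  fail_miss <- !fail_het & missr > miss_max
  keep_ids <- panel$individual_ids[!(fail_het | fail_miss)]
  if (!length(keep_ids)) stop("no samples survive QC")
  out <- subset_individuals(panel, keep_ids)
  report <- new_qc_report(
    "sample",
    list(het = sum(fail_het), missing = sum(fail_miss)),
    list(het_f_bounds = het_f_bounds, miss_max = miss_max),
    n_individuals(panel), length(keep_ids)
  )
  list(panel = out, report = report)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` (or list of them).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
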