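#' Birth-year LOESS curves of ancestry proportions
#'
#' Fits, per reference group, a local regression (degree-2, tricube
#' weights) of the individual ancestry proportions on birth year, and
#' evaluates fit and pointwise 95% confidence band on the year grid. The
#' smoothed components are renormalized to the simplex at each grid year;
#' the raw per-component fits are returned alongside.
#'
#' @param profiles matrix of profiles (rows = individuals, columns =
#'   reference groups).
#' @param birth_years numeric vector parallel to the profile rows.
#' @param span LOESS smoothing parameter (default 0.5).
#' @param year_grid years at which to evaluate (default all years in range).
#' @return data.frame with columns `year`, `group`, `fit` (renormalized),
#'   `lo`, `hi` (renormalized band ends), `fit_raw`.
#' @export
loess_curves <- function(profiles, birth_years, span = 0.5, year_grid = NULL) {
  stopifnot(nrow(profiles) == length(birth_years))
  if (nrow(profiles) < 10L) stop("need at least 10 individuals")
  if (is.null(year_grid)) {
    year_grid <- seq(min(birth_years), max(birth_years))
  }
  fits <- ses <- matrix(0, length(year_grid), ncol(profiles),
                        dimnames = list(year_grid, colnames(profiles)))
  for (g in colnames(profiles)) {
    df <- data.frame(y = profiles[, g], year = birth_years)
    lo <- tryCatch(
      stats::loess(y ~ year, data = df, span = span, degree = 2,
                   family = "gaussian"),
      error = function(e) stop("LOESS failed (", conditionMessage(e),
                               "); try a larger span", call. = FALSE)
    )
    pr <- stats::predict(lo, newdata = data.frame(year = year_grid), se = TRUE)
    fits[, g] <- pr$fit
    ses[, g] <- pr$se.fit
  }
  raw <- fits
  clamped <- pmax(fits, 0)
  norm <- rowSums(clamped)
  norm[norm == 0] <- 1
  fitn <- clamped / norm
  lo_b <- pmax(fits - 1.96 * ses, 0) / norm
  hi_b <- pmax(fits + 1.96 * ses, 0) / norm
  data.frame(
    year = rep(as.numeric(year_grid), times = ncol(profiles)),
    group = rep(colnames(profiles), each = length(year_grid)),
    fit = as.vector(fitn), lo = as.vector(lo_b), hi = as.vector(hi_b),
    fit_raw = as.vector(raw),
    stringsAsFactors = FALSE
  )
}

#' Entropy of an ancestry profile
#'
#' `H = -sum p_i log2 p_i` with `0 log 0 := 0`; ranges from 0 (all mass in
#' one group) to `log2 k` (uniform over k groups).
#'
#' @param profile non-negative numeric vector (a simplex profile).
#' @return entropy in bits.
#' @export
profile_entropy <- function(profile) {
  if (any(profile < 0)) stop("negative profile entry")
  p <- profile[profile > 0]
  -sum(p * log2(p))
}

#' Rate of change of profile heterogeneity over birth years
#'
#' Weighted least-squares regression of yearly entropy on birth year, each
#' year weighted by the number of individuals behind its yearly mean
#' profile. The period can be the full span, the years up to and including
#' the split year, or the years after it.
#'
#' @param yearly_entropy named numeric vector (names = years).
#' @param yearly_n sample count per year (same order).
#' @param period `"full"`, `"pre"` or `"post"` (default `"full"`).
#' @param split_year boundary year; the pre period includes it
#'   (default 1950).
#' @return list with `slope` (entropy units per year), `se`, `period`,
#'   `n_years`.
#' @export
heterogeneity_slope <- function(yearly_entropy, yearly_n,
                                period = c("full", "pre", "post"),
                                split_year = 1950) {
  period <- match.arg(period)
  years <- as.numeric(names(yearly_entropy))
  stopifnot(length(yearly_n) == length(yearly_entropy))
  keep <- yearly_n > 0
  keep <- keep & switch(period,
    full = TRUE,
    pre = years <= split_year,
    post = years > split_year
  )
  if (sum(keep) < 3L) stop("need at least 3 years with data in period")
  fit <- stats::lm(yearly_entropy[keep] ~ years[keep], weights = yearly_n[keep])
  co <- summary(fit)$coefficients
  list(slope = unname(co[2, 1]), se = unname(co[2, 2]),
       period = period, n_years = sum(keep))
}

#' Yearly mean profiles and entropies
#'
#' Averages individual profiles per birth year and computes the entropy of
#' each yearly mean; years without individuals are absent.
#'
#' @param profiles matrix of profiles (rows = individuals).
#' @param birth_years numeric vector parallel to the profile rows.
#' @return list with `mean_profiles` (years x groups), `entropy` (named
#'   numeric) and `n` (named integer).
#' @export
yearly_entropy <- function(profiles, birth_years) {
  yrs <- sort(unique(birth_years))
  mp <- t(vapply(yrs, function(y) colMeans(profiles[birth_years == y, , drop = FALSE]),
                 numeric(ncol(profiles))))
  rownames(mp) <- yrs
  colnames(mp) <- colnames(profiles)
  n <- vapply(yrs, function(y) sum(birth_years == y), integer(1))
  list(mean_profiles = mp,
       entropy = stats::setNames(apply(mp, 1, profile_entropy), yrs),
       n = stats::setNames(n, yrs))
}

#' Mean inbreeding coefficient per region
#'
#' Per-individual method-of-moments F (as in [inbreeding_f()]) averaged
#' over the individuals of each region, with a standard error.
#'
#' @param panel a `haplotype_panel`.
#' @param region_assignment named vector id -> region label.
#' @return data.frame with columns `region`, `mean_f`, `se`, `n`.
#' @export
mean_inbreeding <- function(panel, region_assignment) {
  f <- inbreeding_f(panel)
  ids <- intersect(names(region_assignment), names(f))
  regions <- unique(unname(region_assignment[ids]))
  out <- lapply(regions, function(r) {
    fi <- f[ids[region_assignment[ids] == r]]
    data.frame(region = r, mean_f = mean(fi),
               se = stats::sd(fi) / sqrt(length(fi)), n = length(fi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# per-site Hudson FST components for two allele-frequency/count vectors
hudson_components <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Pairwise Hudson F_ST between groups
#'
#' Ratio-of-averages Hudson estimator per pair of groups, with standard
#' errors from a delete-one block jackknife over chromosomes.
#'
#' @param panel a `haplotype_panel`.
#' @param group_assignment named vector id -> group label; every group
#'   needs at least 5 diploids, and the panel at least 100 variants.
#' @return list with `fst` (symmetric matrix, zero diagonal) and `se`.
#' @export
pairwise_fst <- function(panel, group_assignment) {
  ids <- intersect(names(group_assignment), panel$individual_ids)
  groups <- split(ids, unname(group_assignment[ids]))
  if (any(vapply(groups, length, integer(1)) < 5L)) {
    stop("every group needs at least 5 diploids")
  }
  if (n_variants(panel) < 100L) stop("need at least 100 variants")
  gnames <- names(groups)
  K <- length(gnames)

  # per-chromosome allele frequencies and allele counts per group
  freq <- lapply(names(panel$chromosomes), function(nm) {
    ch <- panel$chromosomes[[nm]]
    lapply(groups, function(g) {
      rows <- as.vector(vapply(g, function(id) hap_rows(panel, id), integer(2)))
      H <- ch$haplotypes[rows, , drop = FALSE]
      n_obs <- colSums(!is.na(H))
      list(p = colSums(H, na.rm = TRUE) / pmax(n_obs, 1L), n = n_obs)
    })
  })
  names(freq) <- names(panel$chromosomes)

  fst <- se <- matrix(0, K, K, dimnames = list(gnames, gnames))
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    per_chrom <- vapply(names(freq), function(nm) {
      a <- freq[[nm]][[i]]; b <- freq[[nm]][[j]]
      poly <- (a$p + b$p) > 0 & (a$p + b$p) < 2 & a$n > 1 & b$n > 1
      if (!any(poly)) return(c(0, 0))
      hc <- hudson_components(a$p[poly], a$n[poly], b$p[poly], b$n[poly])
      c(sum(hc$num), sum(hc$den))
    }, numeric(2))
    tot <- rowSums(per_chrom)
    if (tot[2] <= 0) stop("no polymorphic variants between groups ",
                          gnames[i], " and ", gnames[j])
    est <- tot[1] / tot[2]
    B <- ncol(per_chrom)
    if (B > 1L) {
      jk <- vapply(seq_len(B), function(b) {
        t2 <- tot - per_chrom[, b]
        if (t2[2] <= 0) est else t2[1] / t2[2]
      }, numeric(1))
      se_ij <- sqrt((B - 1) / B * sum((jk - mean(jk))^2))
    } else {
      se_ij <- NA_real_
    }
    fst[i, j] <- fst[j, i] <- est
    se[i, j] <- se[j, i] <- se_ij
  }
  list(fst = fst, se = se)
}
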