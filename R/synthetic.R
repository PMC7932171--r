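#' Describe one synthetic subpopulation
#'
#' The generator follows a Balding-Nichols construction: subpopulation
#' allele frequencies are Beta-distributed around a shared ancestral
#' frequency with differentiation parameter `fst_to_root`. Geographic
#' structure is an isotropic normal scatter of birth places around
#' `center_xy` on a planar km grid.
#'
#' @param name population label.
#' @param center_xy numeric length-2, km.
#' @param dispersion_km standard deviation of the birth-place scatter.
#' @param n_individuals number of sampled diploids.
#' @param founder_pool_size number of founder haplotypes behind the
#'   population (default 30); smaller pools give stronger shared-segment
#'   structure for the copying model to detect.
#' @param fst_to_root differentiation parameter in (0, 1).
#' @param founder_segment_cm mean length (cM) of the founder segments that
#'   make up a sampled haplotype (default 5); the mosaic emulates several
#'   generations of recombination within the founder pool.
#' @param birth_year_range inclusive span of birth years (default 1923-1987).
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(name, center_xy, dispersion_km = 20,
                            n_individuals = 50, founder_pool_size = 30,
                            fst_to_root = 0.05, founder_segment_cm = 5,
                            birth_year_range = c(1923, 1987)) {
  stopifnot(n_individuals >= 1, length(center_xy) == 2)
  if (!(fst_to_root > 0 && fst_to_root < 1)) stop("fst_to_root must be in (0,1)")
  if (fst_to_root < 1e-6) {
    stop("fst_to_root too small: Beta parameters overflow; use >= 1e-6")
  }
  structure(list(
    name = as.character(name), center_xy = as.numeric(center_xy),
    dispersion_km = dispersion_km, n_individuals = as.integer(n_individuals),
    founder_pool_size = as.integer(founder_pool_size),
    fst_to_root = fst_to_root, founder_segment_cm = founder_segment_cm,
    birth_year_range = birth_year_range
  ), class = "population_spec")
}

#' Default synthetic genome map
#'
#' 22 chromosomes at a uniform 1 cM/Mb, with lengths scaled so the genome
#' totals about 3,000 cM, mimicking genome-wide scale at reduced density.
#'
#' @param n_chrom number of chromosomes (default 22).
#' @param total_cm total map length (default 3000).
#' @return genetic map data.frame (see [read_genetic_map()]).
#' @export
default_genetic_map <- function(n_chrom = 22, total_cm = 3000) {
  # linearly decreasing lengths, roughly human-like proportions
  w <- rev(seq_len(n_chrom)) + n_chrom / 2
  len_cm <- total_cm * w / sum(w)
  uniform_genetic_map(stats::setNames(len_cm * 1e6 + 1, paste0("chr", seq_len(n_chrom))))
}

# evenly spaced variant positions across the chromosomes of a map,
# allocated proportionally to physical length
allocate_variants <- function(genetic_map, n_variants) {
  chroms <- unique(genetic_map$chrom)
  lens <- vapply(chroms, function(cc) {
    gm <- genetic_map[genetic_map$chrom == cc, ]
    max(gm$position) - min(gm$position)
  }, numeric(1))
  n_per <- pmax(2L, round(n_variants * lens / sum(lens)))
  out <- list()
  for (i in seq_along(chroms)) {
    gm <- genetic_map[genetic_map$chrom == chroms[i], ]
    pos <- round(seq(min(gm$position), max(gm$position), length.out = n_per[i]))
    pos <- unique(pos)
    out[[chroms[i]]] <- list(
      positions = as.integer(pos),
      cm = interpolate_cm(genetic_map, chroms[i], pos)
    )
  }
  out
}

#' Simulate a structured haplotype panel with metadata and truth labels
#'
#' Balding-Nichols founders with linkage disequilibrium created through
#' recombination: (1) ancestral frequencies are Uniform(0.05, 0.95);
#' (2) per-population frequencies are Beta with parameters
#' `p (1 - F) / F` and `(1 - p)(1 - F) / F`; (3) founder haplotypes are
#' drawn site-wise from the population frequencies; (4) each sampled
#' individual is built by recombining two random founder haplotypes per
#' parent through the meiosis sampler, so shared founder segments induce
#' within-population haplotype structure; (5) birth coordinates are an
#' isotropic normal around the population centre; (6) birth years are
#' uniform over the configured span. Deterministic given `seed`.
#'
#' @param specs list of [population_spec()] objects (at least 2).
#' @param n_variants total variants across the genome (at least 100).
#' @param genetic_map map data.frame (default [default_genetic_map()] with
#'   4 chromosomes at desk scale).
#' @param seed integer seed.
#' @return list with `panel` (`haplotype_panel`), `metadata` (data.frame)
#'   and `truth` (list with `origin`, a named vector, and `admixed`, a list
#'   recording planted pedigrees).
#' @export
simulate_panel <- function(specs, n_variants, genetic_map = NULL, seed = 1L) {
  if (length(specs) < 2L) stop("need at least 2 population specs")
  if (n_variants < 100L) stop("need at least 100 variants")
  stopifnot(all(vapply(specs, inherits, logical(1), "population_spec")))
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated population names")
  if (is.null(genetic_map)) genetic_map <- default_genetic_map(n_chrom = 4, total_cm = 400)
  set.seed(seed)

  sites <- allocate_variants(genetic_map, n_variants)
  chrom_names <- names(sites)
  n_sites <- vapply(sites, function(s) length(s$positions), integer(1))
  L_tot <- sum(n_sites)
  p_anc <- stats::runif(L_tot, 0.05, 0.95)

  pop_freq <- lapply(specs, function(sp) {
    F <- sp$fst_to_root
    stats::rbeta(L_tot, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  })

  ids <- unlist(lapply(specs, function(sp) paste0(sp$name, "_", seq_len(sp$n_individuals))))
  n_ind <- length(ids)
  chroms <- lapply(sites, function(s) {
    list(positions = s$positions, cm = s$cm,
         haplotypes = matrix(0L, nrow = 2L * n_ind, ncol = length(s$positions)))
  })

  offs <- c(0L, cumsum(n_sites))
  row0 <- 0L
  meta_rows <- list()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    # founder haplotypes, site-independent given population frequencies
    # founder haplotypes realize the Balding-Nichols population frequency
    # exactly (rounded allele counts on random founders), so pairwise
    # differentiation is governed by the Beta draw alone and not inflated
    # by founder-pool drift even when the pool is small
    S0 <- sp$founder_pool_size
    founders <- matrix(0L, nrow = S0, ncol = L_tot)
    ones <- pmin(pmax(round(S0 * pop_freq[[k]]), 0L), S0)
    for (j in which(ones > 0L)) {
      founders[sample.int(S0, ones[j]), j] <- 1L
    }
    # each sampled haplotype is a mosaic of founder segments with mean
    # length founder_segment_cm, the stationary outcome of several
    # generations of recombination within the founder pool; sharing is
    # thereby spread evenly over population members instead of being
    # concentrated in sib-like pairs
    for (i in seq_len(sp$n_individuals)) {
      for (hap in 1:2) {
        for (ci in seq_along(chrom_names)) {
          cols <- (offs[ci] + 1L):offs[ci + 1L]
          cm <- chroms[[ci]]$cm
          Lc <- length(cm)
          switch_p <- 1 - exp(-diff(cm) / sp$founder_segment_cm)
          seg <- cumsum(c(1L, stats::runif(Lc - 1L) < switch_p))
          src <- sample.int(S0, max(seg), replace = TRUE)[seg]
          chroms[[ci]]$haplotypes[row0 + 2L * (i - 1L) + hap, ] <-
            founders[cbind(src, cols)]
        }
      }
    }
    xy <- cbind(stats::rnorm(sp$n_individuals, sp$center_xy[1], sp$dispersion_km),
                stats::rnorm(sp$n_individuals, sp$center_xy[2], sp$dispersion_km))
    pxy1 <- xy + matrix(stats::rnorm(2L * sp$n_individuals, 0, sp$dispersion_km / 4), ncol = 2)
    pxy2 <- xy + matrix(stats::rnorm(2L * sp$n_individuals, 0, sp$dispersion_km / 4), ncol = 2)
    meta_rows[[k]] <- data.frame(
      id = ids[row0 / 2L + seq_len(sp$n_individuals)],
      birth_year = sample(seq(sp$birth_year_range[1], sp$birth_year_range[2]),
                          sp$n_individuals, replace = TRUE),
      x = xy[, 1], y = xy[, 2],
      parent1_x = pxy1[, 1], parent1_y = pxy1[, 2],
      parent2_x = pxy2[, 1], parent2_y = pxy2[, 2],
      region = sp$name, municipality_id = k,
      stringsAsFactors = FALSE
    )
    row0 <- row0 + 2L * sp$n_individuals
  }

  panel <- haplotype_panel(chroms, ids)
  origin <- stats::setNames(rep(nm, vapply(specs, `[[`, integer(1), "n_individuals")), ids)
  list(
    panel = panel,
    metadata = do.call(rbind, meta_rows),
    truth = list(origin = origin, admixed = list())
  )
}

#' Plant admixed individuals with known ancestor origins
#'
#' Appends simulated individuals built by [simulate_descendant()] from
#' ancestors sampled out of the existing panel according to a recipe. Each
#' recipe entry gives the origin label of every ancestor slot (length
#' `2^G`); ancestors are drawn without replacement within one simulated
#' individual.
#'
#' @param sim result of [simulate_panel()] (list with `panel` and `truth`).
#' @param recipe list of character vectors; entry `j` holds the origin
#'   labels of the `2^G_j` ancestor slots of planted individual `j`.
#' @param seed integer seed.
#' @param id_prefix prefix for the new individuals' ids (default "adm").
#' @return `sim` with the planted individuals appended to `panel` and their
#'   pedigrees recorded under `truth$admixed`.
#' @export
plant_admixed_individuals <- function(sim, recipe, seed = 1L, id_prefix = "adm") {
  set.seed(seed)
  panel <- sim$panel
  truth <- sim$truth
  base_ids <- names(truth$origin)
  n_existing <- length(truth$admixed)
  new_chroms <- lapply(panel$chromosomes, function(ch) {
    list(positions = ch$positions, cm = ch$cm,
         haplotypes = matrix(0L, nrow = 0L, ncol = length(ch$positions)))
  })
  new_ids <- character(0)
  for (j in seq_along(recipe)) {
    origins <- as.character(recipe[[j]])
    G <- as.integer(round(log2(length(origins))))
    if (2^G != length(origins)) stop("recipe entry ", j, " is not a power of two")
    anc <- character(length(origins))
    used <- character(0)
    for (s in seq_along(origins)) {
      avail <- setdiff(base_ids[truth$origin == origins[s]], used)
      if (!length(avail)) stop("insufficient ancestors of origin '", origins[s], "'")
      anc[s] <- if (length(avail) == 1L) avail else sample(avail, 1L)
      used <- c(used, anc[s])
    }
    des <- simulate_descendant(pedigree(anc), panel)
    id <- paste0(id_prefix, n_existing + j)
    new_ids <- c(new_ids, id)
    for (nm in names(new_chroms)) {
      new_chroms[[nm]]$haplotypes <- rbind(
        new_chroms[[nm]]$haplotypes, des$chromosomes[[nm]]$haplotypes)
    }
    truth$admixed[[id]] <- list(
      G = G, ancestor_ids = anc, ancestor_origins = origins,
      truth_fractions = des$truth_fractions
    )
  }
  add <- haplotype_panel(new_chroms, new_ids)
  sim$panel <- bind_individuals(panel, add)
  sim$truth <- truth
  sim
}
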