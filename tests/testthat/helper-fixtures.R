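# shared fixtures and independent oracles, built in code at test time

fs_cache <- new.env(parent = emptyenv())

gm4 <- function() uniform_genetic_map(stats::setNames(rep(50e6, 4), paste0("chr", 1:4)))

# desk-scale two-population panel (F = 0.05) with reference candidates,
# coancestry tree and a selected 2-group reference set; memoised because
# several test files exercise it
twopop_fixture <- function() {
  if (!is.null(fs_cache$twopop)) return(fs_cache$twopop)
  specs <- list(
    population_spec("A", c(0, 0), dispersion_km = 15, n_individuals = 52,
                    fst_to_root = 0.05),
    population_spec("B", c(200, 0), dispersion_km = 15, n_individuals = 40,
                    fst_to_root = 0.05)
  )
  sim <- simulate_panel(specs, 400, gm4(), seed = 11)
  cand <- c(paste0("A_", 1:24), paste0("B_", 1:24))
  co <- coancestry(sim$panel, cand, switch_rate = 50, mutation_prob = 1e-4)
  tree <- build_population_tree(co)
  refset <- select_reference_groups(tree, sim$panel, K_start = 2,
                                    member_min = 0.7, switch_rate = 50,
                                    mutation_prob = 1e-4)
  orig <- sim$truth$origin
  group_of <- vapply(refset$groups, function(g) {
    names(which.max(table(orig[g])))
  }, character(1))
  fs_cache$twopop <- list(sim = sim, candidates = cand, coancestry = co,
                          tree = tree, refset = refset,
                          truth_group = group_of)
  fs_cache$twopop
}

# small deterministic panel: n diploids, one chromosome, given haplotype matrix
toy_panel <- function(H, cm = NULL, positions = NULL, ids = NULL) {
  n_ind <- nrow(H) / 2
  L <- ncol(H)
  if (is.null(positions)) positions <- seq_len(L) * 1000L
  if (is.null(cm)) cm <- seq(0, by = 1, length.out = L)
  if (is.null(ids)) ids <- paste0("s", seq_len(n_ind))
  haplotype_panel(list(chr1 = list(positions = as.integer(positions),
                                   cm = cm, haplotypes = H)), ids)
}

# panel with prescribed genotype counts at one variant (plus filler variants
# that pass every QC filter)
panel_from_genotypes <- function(dosages, n_filler = 3) {
  n <- length(dosages)
  hap <- matrix(0L, nrow = 2 * n, ncol = 1 + n_filler)
  for (i in seq_len(n)) {
    hap[2 * i - 1, 1] <- as.integer(dosages[i] >= 1)
    hap[2 * i, 1] <- as.integer(dosages[i] == 2)
  }
  set.seed(99)
  for (j in seq_len(n_filler)) {
    g <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    hap[seq(1, 2 * n, 2), 1 + j] <- as.integer(g >= 1)
    hap[seq(2, 2 * n, 2), 1 + j] <- as.integer(g == 2)
  }
  toy_panel(hap)
}

# --- independent oracles -------------------------------------------------

# exhaustive path-sum oracle for the copying model on tiny instances
enum_paint_oracle <- function(r, D, cm, switch_rate, mutation_prob) {
  H <- nrow(D); L <- ncol(D)
  d <- diff(cm)
  stay <- exp(-switch_rate * d / H)
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), L)))
  w <- apply(paths, 1, function(s) {
    p <- 1 / H * (if (D[s[1], 1] == r[1]) 1 - mutation_prob else mutation_prob)
    if (L > 1) for (t in 2:L) {
      tr <- stay[t - 1] * (s[t] == s[t - 1]) + (1 - stay[t - 1]) / H
      p <- p * tr * (if (D[s[t], t] == r[t]) 1 - mutation_prob else mutation_prob)
    }
    p
  })
  w <- w / sum(w)
  wts <- finescale:::site_cm_weights(cm)
  chunks <- numeric(H); lens <- numeric(H)
  for (k in seq_along(w)) {
    s <- paths[k, ]
    runs <- rle(as.vector(s))$values
    for (u in seq_len(H)) chunks[u] <- chunks[u] + w[k] * sum(runs == u)
    for (t in seq_len(L)) lens[s[t]] <- lens[s[t]] + w[k] * wts[t]
  }
  list(chunks = chunks, lengths = lens)
}

# exact HWE p-value by enumeration of allele-to-slot assignments: all
# choose(2n, nA) placements of the minor alleles are equally likely given
# the allele counts; heterozygote-count probabilities follow by counting
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_bb + n_ab  # count the rarer-coded allele consistently
  slots <- utils::combn(2 * n, nA)
  hets <- apply(slots, 2, function(sel) {
    carrier <- tabulate(ceiling(sel / 2), nbins = n)
    sum(carrier == 1)
  })
  tab <- table(hets) / ncol(slots)
  p_obs <- tab[[as.character(n_ab)]]
  sum(tab[tab <= p_obs * (1 + 1e-12)])
}

# dense grid search over the 3-simplex for the mixture estimator
grid_search_simplex <- function(target, V, step = 0.001) {
  w1 <- seq(0, 1, by = step)
  grid <- do.call(rbind, lapply(w1, function(a) {
    b <- seq(0, 1 - a, by = step)
    cbind(a, b, 1 - a - b)
  }))
  R <- grid %*% V
  obj <- rowSums((R - matrix(target, nrow(R), length(target), byrow = TRUE))^2)
  list(w = grid[which.min(obj), ], obj = min(obj))
}

# Hudson ratio-of-averages F_ST recomputed directly from allele frequencies
hudson_oracle <- function(panel, ids1, ids2) {
  num <- den <- 0
  for (nm in names(panel$chromosomes)) {
    ch <- panel$chromosomes[[nm]]
    rows1 <- as.vector(vapply(ids1, function(id) finescale:::hap_rows(panel, id), integer(2)))
    rows2 <- as.vector(vapply(ids2, function(id) finescale:::hap_rows(panel, id), integer(2)))
    p1 <- colMeans(ch$haplotypes[rows1, , drop = FALSE])
    p2 <- colMeans(ch$haplotypes[rows2, , drop = FALSE])
    n1 <- length(rows1); n2 <- length(rows2)
    poly <- (p1 + p2) > 0 & (p1 + p2) < 2
    num <- num + sum((p1[poly] - p2[poly])^2 -
                       p1[poly] * (1 - p1[poly]) / (n1 - 1) -
                       p2[poly] * (1 - p2[poly]) / (n2 - 1))
    den <- den + sum(p1[poly] * (1 - p2[poly]) + p2[poly] * (1 - p1[poly]))
  }
  num / den
}

# Rand-type agreement between two labelings (1 = identical partitions)
partition_agreement <- function(a, b) {
  mean(outer(a, a, "==") == outer(b, b, "=="))
}

write_tiny_vcf <- function(path, body_lines, samples = c("s1", "s2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines
  ), path)
  path
}
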