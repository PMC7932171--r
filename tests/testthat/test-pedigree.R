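test_that("gametes obey Mendelian constraints and map limits", {
  set.seed(22)
  L <- 30
  parent <- list(chr1 = list(cm = rep(0, L),
                             haps = matrix(rbinom(2 * L, 1, 0.5), 2, L)))
  # zero map distance everywhere: gamete equals one parental haplotype intact
  g <- sample_gamete(parent)
  expect_true(identical(g$chr1, parent$chr1$haps[1, ]) ||
                identical(g$chr1, parent$chr1$haps[2, ]))

  parent2 <- list(chr1 = list(cm = seq(0, 100, length.out = L),
                              haps = matrix(rbinom(2 * L, 1, 0.5), 2, L)))
  for (i in 1:20) {
    g2 <- sample_gamete(parent2)$chr1
    expect_true(all(g2 == parent2$chr1$haps[1, ] | g2 == parent2$chr1$haps[2, ]))
  }
  bad <- list(chr1 = list(cm = c(2, 1), haps = matrix(0L, 2, 2)))
  expect_error(sample_gamete(bad), "negative map distance")
})

test_that("crossover counts match the Haldane expectation", {
  L <- 200
  cm <- seq(0, 100, length.out = L)  # one Morgan
  d <- diff(cm) / 100
  expected <- sum((1 - exp(-2 * d)) / 2)  # analytic switch expectation
  set.seed(23)
  counts <- replicate(4000, {
    src <- finescale:::sample_crossover_sources(cm)
    sum(diff(src) != 0)
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # and the expectation is close to the map length in Morgans
  expect_lt(abs(expected - 1), 0.05)
})

test_that("descendant simulation conserves and splits ancestry correctly", {
  set.seed(24)
  H <- matrix(rbinom(16 * 60, 1, 0.5), nrow = 16)
  panel <- toy_panel(H, cm = seq(0, 80, length.out = 60))
  ids <- panel$individual_ids

  # G=1: each parent contributes exactly one gamete, hence exactly 1/2
  d1 <- simulate_descendant(pedigree(ids[1:2]), panel, seed = 1)
  expect_equal(unname(d1$truth_fractions), c(0.5, 0.5))

  # conservation and alleles drawn from the pedigree
  d3 <- simulate_descendant(pedigree(ids[1:8]), panel, seed = 2)
  expect_equal(sum(d3$truth_fractions), 1, tolerance = 1e-12)

  # mean fraction of a designated ancestor at G=3 approaches 1/8
  set.seed(25)
  fr <- replicate(300, {
    d <- simulate_descendant(pedigree(sample(ids)), panel)
    d$truth_fractions[[ids[1]]]
  })
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 1 / 8), 3 * se)

  expect_error(pedigree(c("a", "a")), "reused ancestor")
  expect_error(pedigree(c("a", "b", "c")), "power of two")
})

test_that("scenarios record replicates and classify by the second-largest rule", {
  set.seed(26)
  H <- matrix(rbinom(24 * 40, 1, 0.5), nrow = 24)
  panel <- toy_panel(H, cm = seq(0, 50, length.out = 40))
  ids <- panel$individual_ids
  stub <- function(sim) c(A = 0.9, B = 0.1)
  res <- run_scenario(ids[1:8], NULL, panel, stub, n_replicates = 3, G_range = 1:2)
  expect_equal(nrow(res), 3 * 2 * 2)
  expect_equal(max(res$replicate), 3)
  expect_equal(formals(run_scenario)$n_replicates, 20L)
  expect_error(run_scenario(ids[1:3], NULL, panel, stub, n_replicates = 1,
                            G_range = 2), "exhausted")

  # perfect separation: no Almost- replicate is misassigned as single-origin
  cls <- classify_single_origin(rep(1, 20), rep(0.5, 20))
  expect_equal(cls$misassigned_almost, 0L)
  # threshold is the 19th order statistic for 20 replicates
  vals <- seq(0.8, 0.99, length.out = 20)
  expect_equal(classify_single_origin(vals, numeric(0))$threshold,
               sort(vals)[19])
  # identical distributions: counts match direct enumeration
  v <- c(0.1, 0.4, 0.7, 0.9, 0.95)
  cls2 <- classify_single_origin(v, v)
  thr <- sort(v, decreasing = TRUE)[2]
  expect_equal(cls2$misassigned_almost, sum(v > thr))
  expect_equal(cls2$unrecognized_all, sum(v <= thr))
  expect_error(classify_single_origin(0.9, v), "at least 2")
})

test_that("ancestor-candidate trimming works in both modes", {
  # 10 points on a line: the 8 with smallest axis-1 coordinate are kept
  pc <- cbind(1:10, 0)
  rownames(pc) <- paste0("i", 1:10)
  grp <- stats::setNames(rep("west", 10), rownames(pc))
  kept <- select_ancestor_candidates(pc, grp, mode = "pc1-tail",
                                     poles = c(west = -1))
  expect_setequal(kept$west, paste0("i", 1:8))
  kept_e <- select_ancestor_candidates(pc, grp, mode = "pc1-tail",
                                       poles = c(west = 1))
  expect_setequal(kept_e$west, paste0("i", 3:10))

  # isotropic cloud: highest-50%-density ellipse keeps about half
  set.seed(27)
  cloud <- cbind(rnorm(400), rnorm(400))
  rownames(cloud) <- paste0("c", 1:400)
  grp2 <- stats::setNames(rep("g", 400), rownames(cloud))
  kept2 <- select_ancestor_candidates(cloud, grp2, mode = "density-50")
  expect_lt(abs(length(kept2$g) / 400 - 0.5), 0.08)

  # a far outlier is excluded by the density rule
  cloud2 <- rbind(cbind(rnorm(30, 0, 1), rnorm(30, 0, 1)), c(50, 50))
  rownames(cloud2) <- paste0("d", 1:31)
  grp3 <- stats::setNames(rep("g", 31), rownames(cloud2))
  kept3 <- select_ancestor_candidates(cloud2, grp3, mode = "density-50")
  expect_false("d31" %in% kept3$g)

  expect_error(select_ancestor_candidates(pc[1:4, , drop = FALSE],
                                          grp[1:4], mode = "pc1-tail"),
               "fewer than 5")
})
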