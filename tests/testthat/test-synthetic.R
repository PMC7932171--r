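test_that("the generator is deterministic and validates its inputs", {
  specs <- list(
    population_spec("A", c(0, 0), n_individuals = 6, fst_to_root = 0.05),
    population_spec("B", c(100, 0), n_individuals = 6, fst_to_root = 0.05)
  )
  s1 <- simulate_panel(specs, 120, gm4(), seed = 42)
  s2 <- simulate_panel(specs, 120, gm4(), seed = 42)
  expect_identical(s1$panel$chromosomes, s2$panel$chromosomes)
  expect_identical(s1$metadata, s2$metadata)

  expect_error(simulate_panel(specs[1], 120, gm4()), "at least 2")
  expect_error(simulate_panel(specs, 50, gm4()), "at least 100")
  expect_error(population_spec("A", c(0, 0), fst_to_root = 1e-9), "overflow|1e-6")
  expect_error(population_spec("A", c(0, 0), fst_to_root = 1.2), "0,1")
})

test_that("realized differentiation matches nominal and is monotone in F", {
  specs <- list(
    population_spec("A", c(0, 0), n_individuals = 60, fst_to_root = 0.05),
    population_spec("B", c(200, 0), n_individuals = 60, fst_to_root = 0.05)
  )
  sim <- simulate_panel(specs, 1000, gm4(), seed = 2)
  grp <- stats::setNames(sim$truth$origin, names(sim$truth$origin))
  est <- pairwise_fst(sim$panel, grp)$fst["A", "B"]
  expect_gt(est, 0.05 * 0.7)
  expect_lt(est, 0.05 * 1.3)
  # the packaged estimator agrees with a direct allele-frequency oracle
  oracle <- hudson_oracle(sim$panel, paste0("A_", 1:60), paste0("B_", 1:60))
  expect_equal(unname(est), oracle, tolerance = 1e-10)

  fs <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  realized <- vapply(fs, function(f) {
    sp <- list(population_spec("A", c(0, 0), n_individuals = 30, fst_to_root = f),
               population_spec("B", c(200, 0), n_individuals = 30, fst_to_root = f))
    s <- simulate_panel(sp, 600, gm4(), seed = 13)
    g <- stats::setNames(s$truth$origin, names(s$truth$origin))
    pairwise_fst(s$panel, g)$fst["A", "B"]
  }, numeric(1))
  expect_gt(cor(fs, realized, method = "spearman"), 0.9)
})

test_that("planted admixed individuals obey their recorded pedigree", {
  specs <- list(
    population_spec("A", c(0, 0), n_individuals = 20, fst_to_root = 0.05),
    population_spec("B", c(100, 0), n_individuals = 20, fst_to_root = 0.05)
  )
  sim <- simulate_panel(specs, 150, gm4(), seed = 9)

  # G=1 with both parents from A: Mendelian constraint at every site
  planted <- plant_admixed_individuals(sim, list(c("A", "A")), seed = 4)
  tr <- planted$truth$admixed$adm1
  expect_equal(tr$G, 1L)
  kid <- as_recipient(planted$panel, "adm1")
  for (nm in names(kid)) {
    par1 <- as_recipient(planted$panel, tr$ancestor_ids[1])[[nm]]$haplotypes
    par2 <- as_recipient(planted$panel, tr$ancestor_ids[2])[[nm]]$haplotypes
    ok1 <- kid[[nm]]$haplotypes[1, ] == par1[1, ] |
      kid[[nm]]$haplotypes[1, ] == par1[2, ]
    ok2 <- kid[[nm]]$haplotypes[2, ] == par2[1, ] |
      kid[[nm]]$haplotypes[2, ] == par2[2, ]
    expect_true(all(ok1) && all(ok2))
  }
  expect_equal(sum(tr$truth_fractions), 1)

  # 16-slot recipe records exactly one B ancestor
  planted2 <- plant_admixed_individuals(sim, list(c(rep("A", 15), "B")), seed = 5)
  tr2 <- planted2$truth$admixed$adm1
  expect_equal(length(tr2$ancestor_ids), 16L)
  expect_equal(sum(tr2$ancestor_origins == "B"), 1L)

  # depleted origin is named in the error
  expect_error(
    plant_admixed_individuals(sim, list(rep("A", 64)), seed = 1),
    "origin 'A'")
})

test_that("minor-ancestor genomic fraction averages 1/16 at depth four", {
  specs <- list(
    population_spec("A", c(0, 0), n_individuals = 20, fst_to_root = 0.05),
    population_spec("B", c(100, 0), n_individuals = 20, fst_to_root = 0.05)
  )
  sim <- simulate_panel(specs, 150, gm4(), seed = 21)
  set.seed(31)
  fr <- replicate(80, {
    anc <- c(sample(paste0("A_", 1:20), 15), sample(paste0("B_", 1:20), 1))
    sim2 <- simulate_descendant(pedigree(sample(anc)), sim$panel)
    expect_equal(sum(sim2$truth_fractions), 1, tolerance = 1e-12)
    sum(sim2$truth_fractions[grep("^B", names(sim2$truth_fractions))])
  })
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 1 / 16), 3 * se)
})

test_that("the copying model detects single-origin individuals", {
  fx <- twopop_fixture()
  orig <- fx$sim$truth$origin
  ids <- sample(fx$sim$panel$individual_ids, 40)
  own <- vapply(ids, function(id) {
    cv <- paint_panel_individual(fx$sim$panel, id, switch_rate = 50,
                                 mutation_prob = 1e-4,
                                 donor_units = stats::setNames(orig, names(orig)))
    names(which.max(cv$chunk_counts)) == orig[id]
  }, logical(1))
  expect_gte(mean(own), 0.95)
})
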