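test_that("group copyvectors aggregate and average as plain arithmetic", {
  X <- rbind(a1 = c(P1 = 2, P2 = 4), a2 = c(6, 0), b1 = c(1, 1), b2 = c(3, 5))
  m <- group_copyvectors(X, list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_equal(m$V["A", ], c(P1 = 4, P2 = 2))
  expect_equal(m$V["B", ], c(P1 = 2, P2 = 3))
  # identical members: group vector equals any member
  X2 <- rbind(c1 = c(P1 = 1.5, P2 = 2.5), c2 = c(P1 = 1.5, P2 = 2.5))
  m2 <- group_copyvectors(X2, list(A = c("c1", "c2")))
  expect_equal(m2$V["A", ], X2["c1", ])
  # relabeling symmetry
  m3 <- group_copyvectors(X, list(B = c("b1", "b2"), A = c("a1", "a2")))
  expect_equal(m3$V[c("A", "B"), ], m$V[c("A", "B"), ])
  expect_error(group_copyvectors(X, list(A = character(0))), "empty group")
})

test_that("simplex least squares is exact and matches dense grid search", {
  set.seed(18)
  V <- matrix(runif(3 * 5, 0.5, 2), 3, 5,
              dimnames = list(c("A", "B", "C"), paste0("P", 1:5)))
  model <- structure(list(V = V, n = c(2, 2, 2)), class = "surrogate_model")

  # convex identities
  expect_equal(estimate_profile(V["A", ], model),
               c(A = 1, B = 0, C = 0), tolerance = 1e-9)
  w <- estimate_profile(0.5 * V["A", ] + 0.5 * V["B", ], model)
  expect_equal(unname(w[1:2]), c(0.5, 0.5), tolerance = 1e-6)

  # random targets vs 0.001-step grid search
  for (i in 1:3) {
    tgt <- runif(5, 0, 3)
    w <- estimate_profile(tgt, model)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= -1e-12))
    gs <- grid_search_simplex(tgt, V, step = 0.001)
    obj_ls <- sum((tgt - as.vector(t(V) %*% w))^2)
    expect_lte(obj_ls, gs$obj + 1e-9)
    expect_lt(max(abs(w - gs$w)), 2e-3)
  }
})

test_that("the MCMC estimator approximates a known mixture", {
  set.seed(19)
  V <- matrix(c(100, 10, 5, 10, 100, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("P", 1:3)))
  model <- structure(list(V = V, n = c(2, 2)), class = "surrogate_model")
  tgt <- 300 * (0.7 * V["A", ] + 0.3 * V["B", ]) / sum(V["A", ])
  w <- estimate_profile(tgt, model, method = "mcmc",
                        mcmc_params = list(seed = 3, n_iter = 4000))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_lt(abs(w[["A"]] - 0.7), 0.15)
})

test_that("degenerate models fall back to a uniform profile", {
  V <- matrix(1, 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  model <- structure(list(V = V, n = c(2, 2, 2)), class = "surrogate_model")
  expect_warning(w <- estimate_profile(rep(1, 4), model), "degenerate")
  expect_equal(unname(w), rep(1 / 3, 3))
})

test_that("leave-one-out deflates the group mean exactly", {
  set.seed(20)
  X <- matrix(runif(8 * 3, 1, 4), 8, 3,
              dimnames = list(paste0("m", 1:8), paste0("P", 1:3)))
  groups <- list(A = paste0("m", 1:4), B = paste0("m", 5:8))
  # arithmetic identity: LOO mean = (n * mean - x) / (n - 1)
  model <- group_copyvectors(X, groups)
  loo_mean <- (4 * model$V["A", ] - X["m1", ]) / 3
  expect_equal(loo_mean, colMeans(X[paste0("m", 2:4), ]))

  P <- leave_one_out_profiles(X, groups)
  expect_equal(dim(P), c(8L, 2L))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))

  # 2-member group: each member is estimated against the other alone
  g2 <- list(A = c("m1", "m2"), B = c("m5", "m6"))
  P2 <- leave_one_out_profiles(X[c(1, 2, 5, 6), ], g2)
  direct_model <- structure(
    list(V = rbind(A = X["m2", ], B = colMeans(X[c("m5", "m6"), ])),
         n = c(1, 2)), class = "surrogate_model")
  expect_equal(P2["m1", ], estimate_profile(X["m1", ], direct_model))

  expect_error(leave_one_out_profiles(X, list(A = "m1", B = paste0("m", 5:8))),
               "singleton")
})

test_that("the shrink rule respects its boundary and preserves order", {
  expect_equal(shrink_profile(c(0.93, 0.04, 0.03)), c(1, 0, 0))
  expect_equal(shrink_profile(c(0.6, 0.4)), c(0.6, 0.4))
  # entries exactly at the threshold survive (strict '<')
  expect_equal(shrink_profile(c(0.5, 0.45, 0.05)), c(0.5, 0.45, 0.05))
  # everything below threshold: largest entry kept at 1
  expect_equal(shrink_profile(rep(0.02, 50), threshold = 0.05),
               c(1, rep(0, 49)))

  set.seed(21)
  for (i in 1:20) {
    p <- as.vector(stats::rgamma(6, 0.7)); p <- p / sum(p)
    s <- shrink_profile(p)
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_lte(sum(s > 0), sum(p > 0))
    surv <- which(s > 0)
    expect_equal(order(s[surv]), order(p[surv]))
  }
})

test_that("identity proportions are own-population member means", {
  P <- rbind(x = c(A = 1, B = 0), y = c(A = 0.8, B = 0.2),
             z = c(A = 0.6, B = 0.4), w = c(A = 0.5, B = 0.5))
  assign <- c(x = "A", y = "A", z = "A", w = "B")
  idp <- identity_proportions(P, assign)
  expect_equal(idp[["A"]], mean(c(1, 0.8, 0.6)))
  expect_equal(idp[["B"]], 0.5)
  # uniform profiles over K groups -> identity 1/K
  Pu <- matrix(0.5, 2, 2, dimnames = list(c("x", "y"), c("A", "B")))
  expect_equal(unname(identity_proportions(Pu, c(x = "A", y = "B"))),
               c(0.5, 0.5))
  expect_error(identity_proportions(P[1:2, ], assign), "lacking a profile")
})

test_that("reference selection drops unseparable splits and replays exactly", {
  fx <- twopop_fixture()
  rs <- fx$refset
  # two well-separated populations at K_start = 2: both retained, high
  # identity, no exclusion iterations of the population loop
  expect_length(rs$groups, 2L)
  expect_true(all(rs$identity > 0.9))
  pop_steps <- Filter(function(e) e$step == "population-exclusion", rs$audit)
  expect_length(pop_steps[[1]]$dropped, 0L)

  # constructed unseparable split: population A carries two sub-blocks in
  # the coancestry (so the tree splits it at K = 3) but its members'
  # copyvectors are indistinguishable, forcing an identity-driven exclusion
  # and a rerun of the loop at lower K
  ids <- c(paste0("a", 1:16), paste0("b", 1:8))
  Mc <- matrix(1, 24, 24, dimnames = list(ids, ids))
  Mc[1:16, 1:16] <- 5
  Mc[17:24, 17:24] <- 5
  Mc[1:8, 1:8] <- 8       # planted sub-blocks inside A
  Mc[9:16, 9:16] <- 8
  diag(Mc) <- 0
  tree3 <- build_population_tree(Mc)
  cut3 <- cut_population_tree(tree3, 3)
  expect_equal(length(unique(cut3[paste0("a", 1:16)])), 2L)
  v_A <- c(8, 8, 0); v_B <- c(0, 0, 16)
  X3 <- t(vapply(ids, function(id) if (startsWith(id, "a")) v_A else v_B,
                 numeric(3)))
  colnames(X3) <- unique(unname(cut3))
  rs3 <- select_reference_groups(tree3, panel = NULL, K_start = 3,
                                 basis_level = 3, member_min = 0.7, X = X3)
  pop_steps3 <- Filter(function(e) e$step == "population-exclusion", rs3$audit)
  expect_gte(length(pop_steps3), 2L)
  expect_gte(sum(lengths(lapply(pop_steps3, `[[`, "dropped"))), 1L)
  expect_length(rs3$groups, 2L)

  # stricter member threshold removes a superset of members
  rs95 <- select_reference_groups(fx$tree, fx$sim$panel, K_start = 2,
                                  member_min = 0.95, switch_rate = 50,
                                  mutation_prob = 1e-4)
  kept70 <- unlist(rs$groups); kept95 <- unlist(rs95$groups)
  expect_true(all(kept95 %in% kept70))

  # audit replay reconstructs the final groups without re-estimation
  for (r in list(rs, rs3, rs95)) {
    replay <- replay_reference_audit(r)
    expect_equal(lapply(replay, sort), lapply(r$groups, sort))
  }
})
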