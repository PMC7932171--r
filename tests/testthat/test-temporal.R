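test_that("LOESS curves reproduce constants and linear trends", {
  set.seed(28)
  n <- 60
  years <- sample(1930:1980, n, replace = TRUE)
  P <- matrix(rep(c(0.7, 0.3), each = n), n, 2,
              dimnames = list(NULL, c("A", "B")))
  cr <- loess_curves(P, years)
  expect_true(all(abs(cr$fit[cr$group == "A"] - 0.7) < 1e-6))
  expect_true(all(cr$hi >= cr$lo))
  expect_true(any(cr$hi - cr$lo > 0))
  # renormalized components sum to one at every grid year
  sums <- tapply(cr$fit, cr$year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # linear trend with low noise tracks the least-squares line
  a <- 0.2 + 0.005 * (years - 1930) + rnorm(n, 0, 0.01)
  P2 <- cbind(A = a, B = 1 - a)
  cr2 <- loess_curves(P2, years)
  ols <- lm(a ~ years)
  pred <- predict(ols, newdata = data.frame(years = sort(unique(years))))
  fitA <- cr2$fit[cr2$group == "A"][match(sort(unique(years)),
                                          sort(unique(cr2$year)))]
  expect_lt(max(abs(fitA[!is.na(fitA)] - pred), na.rm = TRUE), 0.05)

  expect_error(loess_curves(P[1:5, ], years[1:5]), "at least 10")
})

test_that("profile entropy matches closed forms and bounds", {
  expect_equal(profile_entropy(c(1, 0, 0)), 0)
  expect_equal(profile_entropy(c(0.5, 0.5)), 1)
  expect_equal(profile_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(profile_entropy(c(-0.1, 1.1)), "negative")
  set.seed(29)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    p <- stats::rgamma(k, 1); p <- p / sum(p)
    H <- profile_entropy(p)
    expect_gte(H, 0)
    expect_lte(H, log2(k) + 1e-12)
  }
  # maximal iff uniform
  expect_equal(profile_entropy(rep(1 / 4, 4)), 2)
  expect_lt(profile_entropy(c(0.4, 0.3, 0.2, 0.1)), 2)
  # shrinking cannot push entropy above the support-size bound
  p <- c(0.5, 0.3, 0.1, 0.06, 0.04)
  s <- shrink_profile(p)
  expect_lte(profile_entropy(s), log2(sum(s > 0)) + 1e-12)
})

test_that("heterogeneity slopes equal weighted least squares", {
  yrs <- 1930:1950
  e_const <- stats::setNames(rep(0.8, length(yrs)), yrs)
  n <- stats::setNames(rep(5, length(yrs)), yrs)
  # a constant series is an exactly perfect fit; the lm warning is expected
  expect_equal(suppressWarnings(heterogeneity_slope(e_const, n)$slope), 0,
               tolerance = 1e-12)

  e_lin <- stats::setNames(0.01 * (yrs - 1923), yrs)
  expect_equal(heterogeneity_slope(e_lin, n)$slope, 0.01, tolerance = 1e-12)

  # unequal weights against the closed-form WLS slope
  y <- c(0.2, 0.5, 0.4, 0.9)
  w <- c(1, 4, 2, 8)
  x <- c(1930, 1940, 1950, 1960)
  names(y) <- x
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  slope_hand <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  expect_equal(heterogeneity_slope(y, w)$slope, slope_hand, tolerance = 1e-12)

  # zero-weight years do not alter the fit
  y2 <- c(y, `1970` = 5); w2 <- c(w, 0)
  expect_equal(heterogeneity_slope(y2, w2)$slope, slope_hand, tolerance = 1e-12)

  # the pre period includes the split year, the post period excludes it
  yrs5 <- c(1948, 1949, 1950, 1951, 1952, 1953)
  e5 <- stats::setNames(seq(0.1, 0.6, by = 0.1), yrs5)
  n5 <- rep(1, 6)
  expect_equal(heterogeneity_slope(e5, n5, "pre")$n_years, 3L)
  expect_equal(heterogeneity_slope(e5, n5, "post")$n_years, 3L)
  expect_error(heterogeneity_slope(e5[1:2], n5[1:2]), "at least 3")
})

test_that("regional inbreeding means behave and reconcile", {
  set.seed(30)
  n <- 30; L <- 300
  H <- matrix(rbinom(2 * n * L, 1, 0.5), nrow = 2 * n)
  # region 'hom': fully homozygous individuals
  for (i in 1:10) H[2 * i, ] <- H[2 * i - 1, ]
  panel <- toy_panel(H)
  regions <- stats::setNames(rep(c("hom", "hw"), c(10, 20)),
                             panel$individual_ids)
  mi <- mean_inbreeding(panel, regions)
  f_hom <- mi$mean_f[mi$region == "hom"]
  f_hw <- mi$mean_f[mi$region == "hw"]
  expect_gt(f_hom, 0.9)
  se_hw <- mi$se[mi$region == "hw"]
  expect_lt(abs(f_hw), 3 * se_hw)
  # regional means reconcile with the global mean as a weighted average
  f_all <- inbreeding_f(panel)
  expect_equal(sum(mi$mean_f * mi$n) / sum(mi$n), mean(f_all), tolerance = 1e-12)
})

test_that("Hudson F_ST is null for split halves and symmetric", {
  fx <- twopop_fixture()
  panel <- fx$sim$panel
  # split-half of one population: estimate within 3 SE of zero
  g <- stats::setNames(rep(c("h1", "h2"), 26), paste0("A_", 1:52))
  res <- pairwise_fst(panel, g)
  expect_lt(abs(res$fst["h1", "h2"]), 3 * res$se["h1", "h2"])
  expect_equal(res$fst, t(res$fst))
  expect_true(all(diag(res$fst) == 0))

  expect_error(pairwise_fst(panel, stats::setNames(rep(c("a", "b"), 2),
                                                   paste0("A_", 1:4))),
               "at least 5")
})
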