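test_that("tangent angles vanish for straight spines and recover arc angles", {
  straight <- make_spine()
  expect_equal(tangent_angle_measure(straight, "frontal"), 0)
  expect_equal(tangent_angle_measure(straight, "sagittal"), 0)
  expect_equal(balance_offsets(straight), c(frontal = 0, sagittal = 0))

  # circular arc subtending 60 degrees, sampled uniformly in arc angle: a
  # circle's chord slope equals the tangent at the mid-angle, so interior
  # central differences are analytically exact and the one-sided ends land
  # half an angular step (60/32 degrees) inside each end, giving exactly
  # 60 - 60/16 degrees for the discrete measure
  phi <- seq(-pi / 6, pi / 6, length.out = 17)
  R <- 400
  sp <- make_spine(x = R * (1 - cos(phi)), z = -R * sin(phi) + 300)
  ang <- tangent_angle_measure(sp, "frontal")
  expect_equal(ang, 60 - 60 / 16, tolerance = 1e-9)
  expect_lt(abs(ang - 60), 4)

  # central differences are exact for quadratic profiles: x = z^2 on
  # equally spaced z has tangent range atan(2) - atan(2/16) interior +
  # one-sided ends which are chords of the parabola (also hand-computable)
  zz <- seq(1, 0, length.out = 17)
  qq <- make_spine(x = zz^2 * 100, z = zz * 100)
  slopes_end <- c((zz[1]^2 - zz[2]^2) / (zz[1] - zz[2]),
                  (zz[16]^2 - zz[17]^2) / (zz[16] - zz[17]))
  slopes_mid <- (zz[3:17]^2 - zz[1:15]^2) / (zz[3:17] - zz[1:15])
  expected <- (atan(max(c(slopes_end, slopes_mid))) -
                 atan(min(c(slopes_end, slopes_mid)))) * 180 / pi
  expect_equal(tangent_angle_measure(qq, "frontal"), expected,
               tolerance = 1e-12)

  expect_error(tangent_angle_measure(straight, "frontal", c("T1", "T2")),
               "at least 3")
  expect_error(tangent_angle_measure(straight, "frontal", c("L5", "T1")),
               "invalid span")
})

test_that("angle surrogates are invariant to translation and isotropic scaling", {
  set.seed(6)
  z <- c(1, sort(runif(15, 0.05, 0.95), decreasing = TRUE), 0) * 430
  sp <- make_spine(x = rnorm(17, 0, 15), y = rnorm(17, 0, 15), z = z)
  base <- spine_measures(sp)
  shifted <- sp
  shifted$coords[, "x"] <- shifted$coords[, "x"] + 50
  shifted$coords[, "y"] <- shifted$coords[, "y"] - 30
  sm <- spine_measures(shifted)
  expect_equal(sm[c("ptc", "mtc", "lc", "tk_t1t12", "tk_t4t12", "ll", "fb", "sb")],
               base[c("ptc", "mtc", "lc", "tk_t1t12", "tk_t4t12", "ll", "fb", "sb")])
  scaled <- sp
  scaled$coords <- scaled$coords * 2.7
  sc <- spine_measures(scaled)
  angle_vars <- c("ptc", "mtc", "lc", "tk_t1t12", "tk_t4t12", "ll")
  expect_equal(sc[angle_vars], base[angle_vars], tolerance = 1e-12)
  expect_equal(unname(sc["fb"]), unname(base["fb"]) * 2.7)

  # balance offsets are the T1 - L5 coordinate differences
  sp2 <- make_spine(x = c(20, rep(5, 15), 0))
  expect_equal(unname(balance_offsets(sp2)["frontal"]), 20)
})

test_that("cluster comparison picks ANOVA for normal data and matches hand-computed F", {
  # hand computation for {1,2,3} vs {7,8,9}: SSB = 54, MSW = 1, F = 54
  x <- c(1, 2, 3, 7, 8, 9)
  g <- rep(1:2, each = 3)
  cmp <- compare_clusters(data.frame(v = x), g)
  expect_identical(cmp$v$test, "anova")
  expect_equal(cmp$v$statistic, 54, tolerance = 1e-10)
  expect_true(cmp$v$significant)

  # two clusters 5 SDs apart are detected with the right direction
  set.seed(10)
  a <- rnorm(20, 0, 1); b <- rnorm(20, 5, 1)
  cmp2 <- compare_clusters(data.frame(v = c(a, b)), rep(1:2, each = 20))
  expect_true(cmp2$v$significant)
  if (cmp2$v$test == "anova") {
    expect_gt(cmp2$v$pairwise$estimate[1], 0)  # Tukey diff is cluster2 - cluster1
  }

  # identical value sets across clusters: F = 0, not significant
  cmp3 <- compare_clusters(data.frame(v = rep(c(1, 2, 3, 4), 3)),
                           rep(1:3, each = 4))
  expect_false(cmp3$v$significant)

  expect_error(compare_clusters(data.frame(v = 1:4), c(1, 1, 1, 2)),
               "at least 3")
})

test_that("non-normal data routes to Kruskal-Wallis with Dunn post-hoc", {
  set.seed(12)
  x <- c(rexp(25, 1)^3, rexp(25, 1)^3 + 8)
  g <- rep(1:2, each = 25)
  cmp <- compare_clusters(data.frame(v = x), g)
  expect_identical(cmp$v$test, "kruskal")
  expect_true(cmp$v$significant)
  expect_identical(nrow(cmp$v$pairwise), 1L)

  # for two groups, Dunn's z^2 equals the Kruskal-Wallis H (no ties)
  d <- dunn_test(x, g)
  H <- kruskal.test(x, factor(g))$statistic
  expect_equal(unname(d$z^2), unname(H), tolerance = 1e-10)
})

test_that("the two-stage omnibus test holds its nominal type-I error", {
  set.seed(2025)
  nsim <- 1000
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    x <- rnorm(45)
    g <- rep(1:3, each = 15)
    cmp <- compare_clusters(data.frame(v = x), g)
    rej[i] <- cmp$v$significant
  }
  rate <- mean(rej)
  mc_se <- sqrt(0.05 * 0.95 / nsim)
  expect_lt(abs(rate - 0.05), 2.5 * mc_se + 1e-9)
})
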