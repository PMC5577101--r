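test_that("the pooled t-test matches hand computation and handles degeneracy", {
  same <- studentsT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  tt <- studentsT(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-10)  # pooled sd = 1
  expect_equal(tt$df, 4)
  expect_equal(tt$t, bfPooledT(c(1, 2, 3), c(2, 3, 4)))
  # zero-variance groups
  flat <- studentsT(c(5, 5), c(5, 5))
  expect_equal(c(flat$t, flat$p), c(0, 1))
  sep <- studentsT(c(5, 5), c(7, 7))
  expect_equal(sep$p, 0)
  expect_true(sep$degenerate)
  # location and scale invariance of t
  a <- c(1.2, 3.4, 2.2, 4.8); b <- c(2.0, 5.1, 3.3)
  expect_equal(studentsT(a + 3, b + 3)$t, studentsT(a, b)$t)
  expect_equal(studentsT(a * 2, b * 2)$t, studentsT(a, b)$t)
})

test_that("one-way ANOVA reproduces the classical decomposition", {
  eq <- oneWayAnova(list(a = c(1, 3), b = c(0, 4), c = c(2, 2)))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  # two groups: F equals t squared
  a <- c(1.5, 2.5, 3.1, 4.2); b <- c(2.2, 3.9, 4.4, 5.0)
  av <- oneWayAnova(list(a = a, b = b))
  expect_equal(av$F, studentsT(a, b)$t^2, tolerance = 1e-10)
  expect_equal(av$p, studentsT(a, b)$p, tolerance = 1e-10)
  # three-group toy set versus direct sums-of-squares arithmetic
  g <- list(g1 = c(1, 2), g2 = c(2, 3), g3 = c(3, 4))
  av3 <- oneWayAnova(g)
  grand <- mean(unlist(g))
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  expect_equal(av3$F, (ssb / 2) / (ssw / 3))
  expect_equal(av3$df_between, 2)
  expect_equal(av3$df_within, 3)
  expect_equal(av3$p, pf((ssb / 2) / (ssw / 3), 2, 3, lower.tail = FALSE))
})

test_that("Student p-values agree with a permutation oracle on small samples", {
  for (s in 1:3) {
    a <- localSeed(s, rnorm(6))
    b <- localSeed(s + 50, rnorm(6, mean = 0.8))
    pT <- studentsT(a, b)$p
    pPerm <- bfPermutationP(a, b, nPerm = 2e4, seed = s)
    mcErr <- 3 * sqrt(pPerm * (1 - pPerm) / 2e4)
    expect_lt(abs(pT - pPerm), 0.03 + mcErr)
  }
})

test_that("Dunnett adjustment collapses to the raw p for a single comparison", {
  g <- list(ctrl = c(1, 2, 3, 4), trt = c(2, 4, 5, 6))
  dn <- dunnettTest(g, control = "ctrl")
  expect_equal(dn$p_adjusted, dn$p_raw)
  expect_equal(dn$p_raw, studentsT(g$trt, g$ctrl)$p, tolerance = 1e-10)
})

test_that("Dunnett adjusted p dominates the raw p and grows with family size", {
  groups <- localSeed(12, list(ctrl = rnorm(5), a = rnorm(5), b = rnorm(5),
                               c = rnorm(5)))
  dn <- dunnettTest(groups, control = "ctrl", nDraws = 2e4, seed = 5)
  expect_true(all(dn$p_adjusted >= dn$p_raw - 1e-12))
  expect_true(all(dn$p_adjusted <= 1))
  # same seed, fewer comparisons: adjusted p of a shared comparison shrinks
  dn2 <- dunnettTest(groups[c("ctrl", "a", "b")], control = "ctrl",
                     nDraws = 2e4, seed = 5)
  shared <- intersect(dn$comparison, dn2$comparison)
  expect_true(all(dn2$p_adjusted[match(shared, dn2$comparison)] <=
                    dn$p_adjusted[match(shared, dn$comparison)] + 1e-12))
  expect_error(dunnettTest(groups, control = "nope"),
               class = "ecms_no_control")
})

test_that("Dunnett adjusted p agrees with the multcomp reference", {
  skip_if_not_installed("multcomp")
  groups <- localSeed(31, list(ctrl = rnorm(6), lo = rnorm(6, 0.5),
                               hi = rnorm(6, 1.2)))
  dn <- dunnettTest(groups, control = "ctrl", nDraws = 2e5, seed = 2)
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups),
                                      each = 6), levels = names(groups)))
  ref <- summary(multcomp::glht(stats::aov(value ~ group, data = df),
                                linfct = multcomp::mcp(group = "Dunnett")))
  pRef <- as.numeric(ref$test$pvalues)
  expect_equal(dn$p_adjusted, pRef, tolerance = 0.01)
})

test_that("t and F are invariant to shifting and rescaling all observations", {
  g <- localSeed(8, list(a = rnorm(4), b = rnorm(4, 1), c = rnorm(4, 2)))
  av <- oneWayAnova(g)
  gs <- lapply(g, function(v) 3.7 * v + 11)
  avs <- oneWayAnova(gs)
  expect_equal(avs$F, av$F, tolerance = 1e-10)
  expect_equal(avs$p, av$p, tolerance = 1e-10)
})
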