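test_that("control-group sampling is reproducible, exact-size and guarded", {
  u <- sprintf("P%02d", 1:10)
  g1 <- sampleControlGroups(u, 3, 5, seed = 7, tag = "Q")
  g2 <- sampleControlGroups(u, 3, 5, seed = 7, tag = "Q")
  expect_identical(g1, g2)
  expect_true(all(vapply(g1, length, integer(1)) == 3))
  expect_true(all(vapply(g1, anyDuplicated, integer(1)) == 0))
  # another tag or seed gives different draws
  expect_false(identical(g1, sampleControlGroups(u, 3, 5, seed = 7, tag = "A")))
  expect_false(identical(g1, sampleControlGroups(u, 3, 5, seed = 8, tag = "Q")))
  # boundary: size = |universe|
  full <- sampleControlGroups(u, 10, 2, seed = 1)
  expect_true(all(vapply(full, setequal, logical(1), u)))
  expect_error(sampleControlGroups(u, 11, 5, seed = 1), "exceeds")
})

test_that("proportion and per-node indexes on the toy network", {
  gn <- extractGroupNetwork(toyInteractome(), c("A", "B", "C"))
  expect_equal(proportionIndex(gn), 0.25)       # 1 of 4 incident edges
  expect_equal(perNodeIndex(gn), 2 / 3)         # handshake 2 over 3 present

  onlyA <- extractGroupNetwork(
    makeInteractome(data.frame(a = "A", b = "B")), c("A", "B"))
  expect_equal(proportionIndex(onlyA), 1)
  onlyB <- extractGroupNetwork(
    makeInteractome(data.frame(a = "A", b = "X")), c("A", "B"))
  expect_equal(proportionIndex(onlyB), 0)
  expect_equal(perNodeIndex(onlyB), 0)

  # complete graph on g members: per-node index g - 1
  ids <- paste0("K", 1:5)
  cmb <- t(combn(ids, 2))
  kn <- extractGroupNetwork(makeInteractome(data.frame(cmb)), ids)
  expect_equal(perNodeIndex(kn), 4)

  empty <- extractGroupNetwork(toyInteractome(), "Z9")
  expect_true(is.na(proportionIndex(empty)))
  expect_true(is.na(perNodeIndex(empty)))
})

test_that("per-node denominator variants", {
  # D is a member with only a type-b edge; E is absent from the graph
  inter <- makeInteractome(data.frame(a = c("A", "A", "D"),
                                      b = c("B", "B2", "X")))
  gn <- extractGroupNetwork(inter, c("A", "B", "D", "E"))
  expect_equal(perNodeIndex(gn, "present_members"), 2 / 3)
  expect_equal(perNodeIndex(gn, "typea_nodes"), 1)
  expect_equal(perNodeIndex(gn, "all_members"), 2 / 4)
})

test_that("control normalization: ratios, mean and SEM closed forms", {
  r <- normalizeAgainstControls(0.5, rep(0.25, 5))
  expect_equal(r$ratios, rep(2, 5))
  expect_equal(r$mean, 2)
  expect_equal(r$sem, 0)

  r <- normalizeAgainstControls(1, 1 / c(1, 2, 3, 4, 5))
  expect_equal(r$ratios, c(1, 2, 3, 4, 5))
  expect_equal(r$mean, 3)
  expect_equal(r$sem, sd(1:5) / sqrt(5))
  expect_equal(round(r$sem, 4), 0.7071)

  expect_equal(normalizeAgainstControls(0.4, rep(0.4, 5))$mean, 1)
  expect_error(normalizeAgainstControls(0.5, c(0.2, 0)), "positive")
})

test_that("Yates chi-squared matches the closed form and chisq.test", {
  z <- yatesChi2Test(10, 10, 10, 10)
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)

  z <- yatesChi2Test(10, 20, 30, 40)
  expect_equal(z$statistic, oracleYates(10, 20, 30, 40), tolerance = 1e-12)
  expect_equal(z$statistic, 0.446428571, tolerance = 1e-6)

  # scaling all counts inflates the statistic
  expect_gt(yatesChi2Test(100, 200, 300, 400)$statistic, z$statistic)

  set.seed(11)
  for (i in 1:20) {
    cnt <- sample(1:80, 4, replace = TRUE)
    expect_equal(yatesChi2Test(cnt[1], cnt[2], cnt[3], cnt[4])$statistic,
                 oracleYates(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
  }
  expect_true(is.na(yatesChi2Test(0, 5, 0, 7)$statistic))
})

test_that("one-way ANOVA: equal means, hand-computed F, degrees of freedom", {
  z <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(z$F, 0)
  expect_equal(z$p.value, 1)

  z <- oneWayAnova(list(c(1, 2), c(3, 4)))
  expect_equal(z$F, 8)                     # SSB = 4, SSW = 1, df (1, 2)
  expect_equal(z$df_between, 1)
  expect_equal(z$df_within, 2)

  z <- oneWayAnova(rep(list(rnorm(5)), 19))
  expect_equal(z$df_between, 18)
  expect_equal(z$df_within, 76)

  z <- oneWayAnova(list(c(1, 1), c(2, 2)))
  expect_equal(z$F, Inf)
  expect_equal(z$p.value, 0)
})

test_that("Dunnett post-hoc: identity, k=1 reduction, adjustment ordering", {
  x <- c(1.1, 0.9, 1.0, 1.05, 0.95)
  d <- dunnettPosthoc(list(ctrl = x, copy = x), control = "ctrl")
  expect_gt(d$table$p_adjusted, 0.99)

  # one comparison: adjusted p equals the pooled-variance two-sample t-test
  set.seed(21)
  a <- rnorm(6); b <- rnorm(6, mean = 1)
  d <- dunnettPosthoc(list(g1 = a, g2 = b), control = "g1")
  tt <- t.test(b, a, var.equal = TRUE)
  expect_equal(d$table$p_adjusted, tt$p.value, tolerance = 1e-4)

  # many-to-one adjustment never falls below the pairwise t-test p
  set.seed(22)
  gs <- lapply(1:6, function(i) rnorm(5, mean = i / 4))
  names(gs) <- paste0("g", 1:6)
  d <- dunnettPosthoc(gs, control = "g1")
  for (i in seq_len(nrow(d$table))) {
    g <- d$table$group[i]
    praw <- t.test(gs[[g]], gs$g1, var.equal = TRUE)$p.value
    expect_gte(d$table$p_adjusted[i] + 1e-8, praw)
  }

  # auto control picks the group with mean ratio closest to 1
  gs$g1 <- gs$g1 + (1 - mean(gs$g1))
  expect_equal(dunnettPosthoc(gs, control = "auto")$control, "g1")
})

test_that("Pearson correlation endpoints and closed form", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  z <- pearsonCorrelation(c(1, 2, 3), c(2, 4, 7))
  # sum of deviation products 5; SS_x = 2, SS_y = 114/9
  expect_equal(z$r, 5 / sqrt(2 * 114 / 9), tolerance = 1e-12)
  expect_equal(round(z$r, 4), 0.9934)
  expect_equal(z$n, 3)
  expect_error(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("indexes are invariant to edges between non-members", {
  base <- data.frame(a = c("A", "A", "B"), b = c("B", "X", "Y"))
  extra <- rbind(base, data.frame(a = c("X", "Y", "Z"),
                                  b = c("Y2", "Z", "W")))
  g <- c("A", "B")
  gn1 <- extractGroupNetwork(makeInteractome(base), g)
  gn2 <- extractGroupNetwork(makeInteractome(extra), g)
  expect_equal(proportionIndex(gn1), proportionIndex(gn2))
  expect_equal(perNodeIndex(gn1), perNodeIndex(gn2))
})

test_that("full group analysis flags a planted group and honors filters", {
  universe <- sprintf("P%03d", 1:120)
  planted <- universe[1:25]
  inter <- simulateInteractome(list(planted), pIn = 0.4, pOut = 0.04,
                               universe, seed = 5)
  groups <- list(Q = planted, W = universe[120],          # singleton
                 M = universe[26:50])                     # null group
  res <- analyzeAllGroups(groups, inter, universe = universe,
                          nControls = 5, seed = 9)
  expect_true("W" %in% res$skipped$group)                 # minGroupSize 2
  q <- res$results[res$results$residue == "Q", ]
  m <- res$results[res$results$residue == "M", ]
  expect_gt(q$mean_norm_proportion, 1.5)
  expect_gt(q$mean_norm_per_node, 1.5)
  expect_true(q$significant)
  expect_lt(abs(m$mean_norm_per_node - 1), 0.5)

  # determinism: same seed reproduces every number
  res2 <- analyzeAllGroups(groups, inter, universe = universe,
                           nControls = 5, seed = 9)
  expect_identical(res$results, res2$results)
  expect_equal(res$anova$F, res2$anova$F)
})
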