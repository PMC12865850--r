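# Frozen reference values for the normality screen were computed with an
# independent implementation of the D'Agostino-Pearson omnibus test on the
# fixed samples below.
normalFixture <- c(
  0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218, 0.12784,
  -0.316243, -0.016801, -0.853044, 0.879398, 0.777792, 0.066031, 1.127241,
  0.467509, -0.859292, 0.368751, -0.958883, 0.87845, -0.049926, -0.184862,
  -0.68093, 1.222541, -0.154529, -0.428328, -0.352134, 0.532309, 0.365444,
  0.412733, 0.430821, 2.141648, -0.406415, -0.512243, -0.813773, 0.615979,
  1.128972, -0.113947, -0.840156, -0.824481, 0.650593, 0.743254, 0.543154,
  -0.66551, 0.232161, 0.116686, 0.218689, 0.871429, 0.223596, 0.678914,
  0.067579)
lognormalFixture <- c(
  1.335251, 1.880031, 0.232898, 0.726388, 0.624769, 0.527884, 0.759464,
  4.459075, 0.420702, 2.633407, 0.18584, 0.71542, 1.176746, 1.797186,
  2.036488, 2.210784, 0.705587, 0.629801, 2.358382, 0.825881, 0.279239,
  0.321973, 0.398737, 1.644047, 1.153067, 1.994683, 0.652299, 1.171798,
  1.869349, 0.733926, 1.578974, 0.515857, 0.695549, 0.682674, 0.30245,
  1.627382, 0.625376, 1.012572, 1.617282, 1.562881, 1.94524, 0.906209,
  0.654883, 0.923377, 0.185012, 0.235249, 0.266415, 0.368894, 1.491488,
  0.404348, 0.685119, 3.666466, 0.700288, 2.090735, 0.393129, 0.814291,
  0.386732, 0.712459, 2.317081, 0.17776)

test_that("normality screen reproduces frozen reference values", {
  r <- normalityTest(normalFixture)
  expect_equal(r$statistic, 0.7077944750, tolerance = 1e-9)
  expect_equal(r$p_value, 0.7019470975, tolerance = 1e-9)
  r2 <- normalityTest(lognormalFixture)
  expect_equal(r2$statistic, 27.0257688638, tolerance = 1e-9)
  expect_equal(r2$p_value, 1.35340836572e-06, tolerance = 1e-6)
})

test_that("normality screen behaves under null and gross non-normality", {
  set.seed(811)
  pNull <- replicate(100, normalityTest(rnorm(2000))$p_value)
  expect_gte(mean(pNull > 0.05), 0.90)
  mix <- c(rnorm(2500, -3), rnorm(2500, 3))
  expect_lt(normalityTest(mix)$p_value, 0.05)
  expect_error(normalityTest(rnorm(10)), "n >= 20")
  expect_error(normalityTest(rep(1, 30)), "variance")
})

test_that("Kruskal-Wallis matches the hand-ranked worked example", {
  kw <- kruskalWallisTrend(list(1:3, 4:6, 7:9))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$effect_size, 0.9, tolerance = 1e-12)
  expect_equal(kw$effect_name, "eta_squared_ranked")
  kwAdj <- kruskalWallisTrend(list(1:3, 4:6, 7:9), effectVariant = "adjusted")
  expect_equal(kwAdj$effect_size, (7.2 - 2) / 6, tolerance = 1e-12)
})

test_that("Kruskal-Wallis agrees with the stock implementation on ties", {
  set.seed(101)
  for (i in 1:20) {
    g <- list(sample(1:5, 15, TRUE), sample(2:6, 12, TRUE),
              sample(1:7, 18, TRUE))
    ref <- stats::kruskal.test(unlist(g),
                               rep(seq_along(g), lengths(g)))
    mine <- kruskalWallisTrend(g)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(103)
  g <- list(rnorm(10), rnorm(12, 0.5), rnorm(8, 1))
  h0 <- kruskalWallisTrend(g)$statistic
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    expect_equal(kruskalWallisTrend(lapply(g, f))$statistic, h0,
                 tolerance = 1e-10)
  }
})

test_that("degenerate group structures error out", {
  expect_error(kruskalWallisTrend(list(1:3)), "2 groups")
  expect_error(kruskalWallisTrend(list(c(1, 1), c(1, 1, 1))), "identical")
  g <- list(1:3, 1:3)
  expect_equal(kruskalWallisTrend(g)$statistic, 0, tolerance = 1e-12)
})

test_that("Dunn post-hoc returns one contrast per pair with capped p", {
  set.seed(107)
  g <- list(Minor = rnorm(15), Moderate = rnorm(15, 5),
            Major = rnorm(15, 5.2))
  d <- dunnPosthoc(g)
  expect_equal(nrow(d), 3)
  expect_true(all(d$p_value <= 1))
  expect_setequal(d$note, c("Moderate_vs_Minor", "Major_vs_Minor",
                            "Major_vs_Moderate"))
  # widely separated pair has the smallest corrected p
  sep <- d$p_value[d$note == "Major_vs_Minor"]
  expect_equal(min(d$p_value), sep)
  # delta signed later-vs-earlier: Major dominates Minor
  expect_gt(d$effect_size[d$note == "Major_vs_Minor"], 0.9)
  caps <- dunnPosthoc(list(rnorm(10), rnorm(10), rnorm(10)))
  expect_true(all(caps$p_value <= 1))
})

test_that("Cliff's delta matches enumeration and is antisymmetric", {
  expect_equal(cliffsDelta(c(10, 11), c(1, 2)), 1)
  expect_equal(cliffsDelta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffsDelta(c(1, 2), c(1, 3)), -0.25)  # 4 pairs: -1 net of 4
  set.seed(109)
  for (i in 1:25) {
    x <- sample(1:6, 8, TRUE); y <- sample(1:6, 5, TRUE)
    # brute force enumeration oracle
    gr <- outer(x, y, ">"); ls <- outer(x, y, "<")
    expect_equal(cliffsDelta(x, y), (sum(gr) - sum(ls)) / (length(x) * length(y)),
                 tolerance = 1e-12)
    expect_equal(cliffsDelta(x, y), -cliffsDelta(y, x), tolerance = 1e-12)
  }
})

test_that("JT worked example: maximal J, exact permutation p", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  jt <- jonckheereTerpstra(g)
  expect_equal(jt$statistic, 12)  # every between-group pair concordant
  expect_lt(jt$p_value, 0.05)
  jtPerm <- jonckheereTerpstra(g, mode = "permutation", nPerm = 500)
  expect_equal(jtPerm$p_value, oracleJtPermutationP(g), tolerance = 1e-12)
  expect_equal(jtPerm$p_value, 1 / 90, tolerance = 1e-12)
  jtDec <- jonckheereTerpstra(g, alternative = "decreasing")
  expect_gte(jtDec$p_value, 0.95)
})

test_that("JT statistic matches the pairwise enumeration oracle with ties", {
  set.seed(113)
  for (i in 1:25) {
    g <- list(sample(1:4, 6, TRUE), sample(1:4, 5, TRUE),
              sample(2:5, 7, TRUE))
    if (length(unique(unlist(g))) == 1) next
    expect_equal(jonckheereTerpstra(g)$statistic, oracleJtStat(g),
                 tolerance = 1e-12)
  }
})

test_that("reversing group order flips Z and swaps directional p-values", {
  set.seed(127)
  g <- list(rnorm(8), rnorm(8, 0.4), rnorm(8, 0.9))
  inc <- jonckheereTerpstra(g, "increasing")
  dec <- jonckheereTerpstra(rev(g), "decreasing")
  expect_equal(dec$z, -inc$z, tolerance = 1e-10)
  expect_equal(dec$p_value, inc$p_value, tolerance = 1e-10)
  expect_equal(jonckheereTerpstra(rev(g), "increasing")$p_value,
               jonckheereTerpstra(g, "decreasing")$p_value,
               tolerance = 1e-10)
})

test_that("JT effect size is Z scaled by the square root of N", {
  set.seed(131)
  g <- list(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  jt <- jonckheereTerpstra(g)
  expect_equal(jt$effect_size, jt$z / sqrt(30), tolerance = 1e-12)
  expect_lte(abs(jt$effect_size), 1)
})

test_that("JT rejects degenerate inputs", {
  expect_error(jonckheereTerpstra(list(numeric(), 1:3)), "at least one")
  expect_error(jonckheereTerpstra(list(c(2, 2), c(2, 2))), "identical")
})

test_that("correlation suite: exact line, monotone transform, errors", {
  x <- seq(1, 10, length.out = 30)
  cs <- correlationSuite(x, 2 * x + 1)
  expect_equal(cs$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cs$r_squared, 1, tolerance = 1e-12)
  expect_equal(cs$slope, 2, tolerance = 1e-10)
  expect_equal(cs$intercept, 1, tolerance = 1e-10)
  # monotone convex transform: rank correlation saturates, linear does not
  csm <- correlationSuite(x, exp(x))
  expect_equal(csm$spearman_rho, 1, tolerance = 1e-12)
  expect_lt(csm$pearson_r, 1)
  expect_error(correlationSuite(1:2, 2:3), "at least 3")
  expect_error(correlationSuite(rep(1, 10), rnorm(10)), "variance")
  set.seed(137)
  ci <- correlationSuite(rnorm(10000), rnorm(10000))
  expect_lt(abs(ci$pearson_r), 0.05)
})
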