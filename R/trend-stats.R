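## Nonparametric trend-testing battery over ordered severity groups.
## All routines are implemented from first principles (rank formulas with
## explicit tie corrections); base R supplies only distribution functions
## and ordinary fits. Results come back as one-row (or few-row) tidy
## data.frames sharing a common column layout so they bind into report
## tables directly.

trendRow <- function(test, statistic, p, effect, effectName, direction,
                     sizes, z = NA_real_, note = "") {
  data.frame(test = test, statistic = statistic, z = z, p_value = p,
             effect_size = effect, effect_name = effectName,
             direction = direction, n = sum(sizes),
             group_sizes = paste(sizes, collapse = "/"),
             note = note, stringsAsFactors = FALSE)
}

#' Build ordered groups from values and ordinal labels
#'
#' Splits a numeric vector by an ordinal label into the list-of-samples
#' form the trend tests consume, in increasing label order (default
#' Minor, Moderate, Major). Pairs with missing value or label are dropped.
#'
#' @param values Numeric vector.
#' @param labels Vector coercible to the ordered severity factor, aligned
#'   with \code{values}.
#' @param levels Group order, lowest first.
#' @return Named list of numeric vectors, one per level, in order.
#' @export
orderedGroups <- function(values, labels, levels = toxicityLevels()) {
  f <- factor(as.character(labels), levels = levels, ordered = TRUE)
  keep <- !is.na(values) & !is.na(f)
  split(values[keep], f[keep], drop = FALSE)
}

checkGroups <- function(groups, minTotal = 2L, allowEmpty = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (!allowEmpty && any(sizes == 0L))
    stop("every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < minTotal)
    stop("need at least ", minTotal, " observations in total")
  if (length(unique(x)) == 1L)
    stop("all values identical; rank tests are undefined")
  invisible(sizes)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness and kurtosis z-approximations into the omnibus
#' statistic \eqn{K^2 = Z_{skew}^2 + Z_{kurt}^2}, referred to a chi-square
#' distribution with 2 degrees of freedom. The z transforms follow
#' D'Agostino's classical moment approximations, which require a minimum
#' sample size; below \code{n = 20} the call errors.
#'
#' @param x Numeric sample, \code{n >= 20}, nonzero variance.
#' @return One-row data.frame (\code{test = "dagostino_pearson"}) with the
#'   \eqn{K^2} statistic and p-value.
#' @export
normalityTest <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20L)
    stop("normality test requires n >= 20 (moment approximations); got n = ", n)
  if (stats::sd(x) == 0) stop("zero variance sample")
  m <- x - mean(x)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)

  # skewness z (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  zSkew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eB2 <- 3 * (n - 1) / (n + 1)
  varB2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eB2) / sqrt(varB2)
  sqrtBeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtBeta1 * (2 / sqrtBeta1 + sqrt(1 + 4 / sqrtBeta1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  zKurt <- (term1 - term2) / sqrt(2 / (9 * A))

  k2 <- zSkew^2 + zKurt^2
  trendRow("dagostino_pearson", k2,
           stats::pchisq(k2, df = 2, lower.tail = FALSE),
           NA_real_, "none", "two_sided", n)
}

# Pooled-rank machinery shared by KW and Dunn: ranks, tie counts.
pooledRanks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  ties <- table(x)
  list(r = split(r, rep(seq_along(groups), lengths(groups))),
       ties = as.vector(ties), N = length(x))
}

#' Kruskal-Wallis rank test with rank eta-squared
#'
#' Tie-corrected H statistic referred to chi-square with k-1 degrees of
#' freedom. The default effect size is the rank eta-squared defined as
#' \eqn{\eta^2 = H/(N-1)} — the proportion of rank variance explained by
#' group membership; \code{effectVariant = "adjusted"} gives the textbook
#' chance-corrected variant \eqn{(H - k + 1)/(N - k)}.
#'
#' @param groups List of numeric samples (order only matters for reporting).
#' @param effectVariant \code{"ranked"} (\eqn{H/(N-1)}, default) or
#'   \code{"adjusted"}.
#' @return One-row data.frame with H, p-value and eta-squared.
#' @export
kruskalWallisTrend <- function(groups, effectVariant = c("ranked", "adjusted")) {
  effectVariant <- match.arg(effectVariant)
  sizes <- checkGroups(groups, minTotal = 5L)
  pr <- pooledRanks(groups)
  N <- pr$N; k <- length(groups)
  sumR2 <- sum(vapply(pr$r, function(ri) sum(ri)^2 / length(ri), numeric(1)))
  H <- 12 / (N * (N + 1)) * sumR2 - 3 * (N + 1)
  C <- 1 - sum(pr$ties^3 - pr$ties) / (N^3 - N)
  H <- H / C
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  eta2 <- switch(effectVariant,
                 ranked = H / (N - 1),
                 adjusted = (H - k + 1) / (N - k))
  trendRow("kruskal_wallis", H, p, eta2,
           paste0("eta_squared_", effectVariant), "two_sided", sizes)
}

#' Cliff's delta dominance effect size
#'
#' \eqn{\delta = (\#\{x_i > y_j\} - \#\{x_i < y_j\}) / (|x||y|)}; ties
#' contribute zero. Computed through midranks in O(n log n).
#'
#' @param x,y Nonempty numeric samples.
#' @return A number in [-1, 1]; positive when \code{x} tends to dominate.
#' @export
cliffsDelta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # #{x>y} + 0.5 ties
  2 * u1 / (n1 * n2) - 1
}

#' Dunn's post-hoc test on mean ranks with Bonferroni correction
#'
#' All pairwise contrasts between the ordered groups on the pooled ranking,
#' with the pooled tie correction in the standard error. The z statistic is
#' signed as (later group mean rank) - (earlier group mean rank), so a
#' positive z means the higher-severity group ranks higher. Two-sided
#' p-values are multiplied by the number of contrasts and capped at 1.
#' Each contrast also carries Cliff's delta (later vs earlier group).
#'
#' @param groups Named list of numeric samples in increasing group order.
#' @param correction Only \code{"bonferroni"}.
#' @return data.frame with one row per contrast; \code{test = "dunn"},
#'   \code{effect_name = "cliffs_delta"}. Column \code{note} names the
#'   contrast as "later_vs_earlier".
#' @export
dunnPosthoc <- function(groups, correction = "bonferroni") {
  correction <- match.arg(correction, "bonferroni")
  sizes <- checkGroups(groups, minTotal = 5L)
  pr <- pooledRanks(groups)
  N <- pr$N
  meanRanks <- vapply(pr$r, mean, numeric(1))
  tieTerm <- sum(pr$ties^3 - pr$ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tieTerm
  k <- length(groups)
  pairs <- utils::combn(k, 2L)
  nPairs <- ncol(pairs)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  rows <- lapply(seq_len(nPairs), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]   # i1 earlier, i2 later
    se <- sqrt(sigma2 * (1 / sizes[i1] + 1 / sizes[i2]))
    z <- (meanRanks[i2] - meanRanks[i1]) / se
    p2 <- 2 * stats::pnorm(-abs(z))
    delta <- cliffsDelta(groups[[i2]], groups[[i1]])
    trendRow("dunn", z, min(1, p2 * nPairs), delta, "cliffs_delta",
             "two_sided", sizes[c(i1, i2)], z = z,
             note = paste0(labs[i2], "_vs_", labs[i1]))
  })
  do.call(rbind, rows)
}

# J statistic: sum over ordered group pairs (i<j) of Mann-Whitney counts
# #{x in g_i, y in g_j : x < y} + 0.5 #{ties}, via midranks.
jtStatistic <- function(groups) {
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      x <- groups[[i]]; y <- groups[[j]]
      n1 <- length(x); n2 <- length(y)
      r <- rank(c(x, y))
      u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # #{x>y} + 0.5 ties
      J <- J + (n1 * n2 - u1)
    }
  }
  J
}

# Tie-corrected null moments of J (Hollander-Wolfe form).
jtNullMoments <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  ni <- lengths(groups)
  tj <- as.vector(table(x))
  mu <- (N^2 - sum(ni^2)) / 4
  A <- N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  v <- A / 72 + B / (36 * N * (N - 1) * (N - 2)) + C / (8 * N * (N - 1))
  list(mean = mu, var = v)
}

# Exhaustive assignments of N items into groups of the given sizes.
# Returns a list of index lists; caller guards the combinatorial count.
enumerateAssignments <- function(N, sizes) {
  rec <- function(remaining, sizes) {
    if (!length(sizes)) return(list(list()))
    first <- utils::combn(remaining, sizes[1L], simplify = FALSE)
    out <- list()
    for (sel in first) {
      rest <- rec(setdiff(remaining, sel), sizes[-1L])
      out <- c(out, lapply(rest, function(r) c(list(sel), r)))
    }
    out
  }
  rec(seq_len(N), sizes)
}

#' Jonckheere-Terpstra ordered trend test
#'
#' Tests for a monotone shift in location across a priori ordered groups.
#' The statistic \eqn{J} sums, over group pairs (i < j), the Mann-Whitney
#' counts of between-group pairs concordant with the ordering, ties
#' half-weighted. In \code{normal_approx} mode \eqn{J} is standardized by
#' its tie-corrected null mean and variance; the Z score is signed so that
#' positive means an increasing trend, and the one-sided p-value follows
#' the requested alternative, with a 0.5 continuity correction on the tail
#' (applied to the p-value only, never to Z or the effect size, since J
#' lives on a half-integer lattice). In \code{permutation} mode the p-value comes
#' from label reshuffles of the pooled values (exhaustive when the number
#' of distinct assignments does not exceed \code{nPerm}, otherwise Monte
#' Carlo with the add-one estimator). The effect size is
#' \eqn{r = Z/\sqrt{N}}, interpretable like a correlation coefficient.
#'
#' @param groups Named list of numeric samples in increasing group order.
#' @param alternative \code{"increasing"} (location rises with group order)
#'   or \code{"decreasing"}.
#' @param mode \code{"normal_approx"} (default) or \code{"permutation"}.
#' @param nPerm Number of shuffles (permutation mode).
#' @param seed Optional integer seed for the Monte Carlo shuffles; the
#'   caller's RNG stream is restored afterwards.
#' @return One-row data.frame with \code{statistic = J}, the Z score, the
#'   one-sided p-value and \code{effect_size = r}.
#' @export
jonckheereTerpstra <- function(groups,
                               alternative = c("increasing", "decreasing"),
                               mode = c("normal_approx", "permutation"),
                               nPerm = 2000L, seed = NULL) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  sizes <- checkGroups(groups, minTotal = 3L)
  J <- jtStatistic(groups)
  mom <- jtNullMoments(groups)
  if (mom$var <= 0) stop("degenerate data: null variance of J is zero")
  Z <- (J - mom$mean) / sqrt(mom$var)
  N <- sum(sizes)
  r <- Z / sqrt(N)

  if (mode == "normal_approx") {
    # J lives on a half-integer lattice; a 0.5 continuity correction on the
    # one-sided tail keeps the approximation aligned with the permutation
    # distribution down to small group sizes. Z and r stay uncorrected.
    s <- sqrt(mom$var)
    p <- if (alternative == "increasing") {
      stats::pnorm((J - 0.5 - mom$mean) / s, lower.tail = FALSE)
    } else {
      stats::pnorm((J + 0.5 - mom$mean) / s)
    }
    note <- "normal_approx"
  } else {
    x <- unlist(groups, use.names = FALSE)
    total <- prod(choose(cumsum(rev(sizes)), rev(sizes)))
    regroup <- function(xx) split(xx, rep(seq_along(sizes), sizes))
    if (is.finite(total) && total <= nPerm) {
      asg <- enumerateAssignments(N, sizes)
      Js <- vapply(asg, function(idx) {
        jtStatistic(lapply(idx, function(i) x[i]))
      }, numeric(1))
      p <- if (alternative == "increasing") mean(Js >= J) else mean(Js <= J)
      note <- sprintf("permutation_exhaustive:%d", length(Js))
    } else {
      Js <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
        jtStatistic(regroup(sample(x)))
      }, numeric(1)))
      hits <- if (alternative == "increasing") sum(Js >= J) else sum(Js <= J)
      p <- (1 + hits) / (nPerm + 1)
      note <- sprintf("permutation_mc:%d", nPerm)
    }
  }
  trendRow("jonckheere_terpstra", J, p, r, "r_z_over_sqrt_n", alternative,
           sizes, z = Z, note = note)
}

#' Pearson, Spearman and least-squares summaries for two variables
#'
#' Product-moment and rank correlations with p-values, plus the ordinary
#' least-squares line of \code{y} on \code{x} and its R-squared (equal to
#' the squared Pearson correlation in simple regression).
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#'   Requires at least 3 complete pairs and nonzero variance in both.
#' @return Named list: \code{pearson_r}, \code{pearson_p},
#'   \code{spearman_rho}, \code{spearman_p}, \code{r_squared},
#'   \code{slope}, \code{intercept}, \code{n}.
#' @export
correlationSuite <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  fit <- stats::lm(y ~ x)
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(x))
}
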