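# brute-force tie-corrected Kruskal-Wallis H, straight from the rank formula
kw_oracle <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# tie-corrected two-sided normal-approximation Wilcoxon p for two samples
wilcox_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq.int(n1 + 1, N)])
  E <- n2 * (N + 1) / 2
  V <- n1 * n2 / (N * (N - 1)) * sum((r - (N + 1) / 2)^2)
  2 * pnorm(abs(W - E) / sqrt(V), lower.tail = FALSE)
}

test_that("Kruskal-Wallis agrees with the brute-force rank formula", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$H, kw_oracle(v, g), tolerance = 1e-8)
  expect_equal(kw$H, 7.2, tolerance = 1e-8)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-10)

  # with ties
  set.seed(31)
  v2 <- sample(rep(1:6, times = 5))
  g2 <- rep(c("a", "b", "c"), each = 10)
  expect_equal(kruskal_wallis(v2, g2)$H, kw_oracle(v2, g2), tolerance = 1e-8)

  # degenerate and symmetry cases
  expect_equal(kruskal_wallis(rep(5, 8), rep(c("a", "b"), 4)),
               list(H = 0, df = 1L, p_value = 1, n = 8L))
  perm <- kruskal_wallis(v, rep(c("c", "a", "b"), each = 3))
  expect_equal(perm$H, kw$H)
})

test_that("Steel-Dwass is symmetric, reduces to Wilcoxon at k = 2, and
           separates distant groups", {
  set.seed(7)
  x <- rnorm(12); y <- rnorm(15, 1); z <- rnorm(9, 2)
  p3 <- steel_dwass(c(x, y, z), rep(c("x", "y", "z"), c(12, 15, 9)))
  expect_true(isSymmetric(p3))
  expect_true(all(is.na(diag(p3))))
  expect_true(all(p3[upper.tri(p3)] >= 0 & p3[upper.tri(p3)] <= 1))

  # k = 2: studentized range with 2 means = two-sided normal Wilcoxon
  p2 <- steel_dwass(c(x, y), rep(c("x", "y"), c(12, 15)))
  expect_equal(p2["x", "y"], wilcox_normal_p(x, y), tolerance = 1e-6)

  sep <- steel_dwass(c(1:10, 101:110), rep(c("lo", "hi"), each = 10))
  expect_lt(sep["lo", "hi"], 0.01)

  expect_error(steel_dwass(c(1, 2, 3), c("a", "a", "b")), "b")
})

test_that("Steel-Dwass p is never below the unadjusted pairwise Wilcoxon p", {
  for (s in 1:5) {
    set.seed(100 + s)
    v <- rnorm(36) + rep(c(0, 0.5, 1), each = 12)
    g <- rep(c("a", "b", "c"), each = 12)
    pm <- steel_dwass(v, g)
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      raw <- wilcox_normal_p(v[g == pair[1]], v[g == pair[2]])
      expect_gte(pm[pair[1], pair[2]], raw - 1e-12)
    }
  }
})

test_that("Brunner-Munzel matches frozen independent reference values", {
  # classic two-sample fixture with heavy ties
  x <- c(1, 2, 1, 1, 1, 1, 1, 1, 1, 1, 2, 4, 1, 1)
  y <- c(3, 3, 4, 3, 1, 2, 3, 1, 1, 5, 4)
  bm <- brunner_munzel(x, y)
  expect_equal(bm$statistic, 3.1374674823029505, tolerance = 1e-8)
  expect_equal(bm$p_value, 0.005786208666151469, tolerance = 1e-8)
  expect_equal(bm$relative_effect, 0.788961038961039, tolerance = 1e-12)

  # tie-free unequal-n fixture
  a <- c(0.001, 0.299, -0.274, -0.891, -0.455, -0.992, 0.06, 1.34, -0.492)
  b <- c(-0.441, 1.78, 1.514, 1.011, -1.061, 0.741, 2.191, -1.888, -0.115,
         -3.002, -1.779, -2.883, 0.33)
  bm2 <- brunner_munzel(a, b)
  expect_equal(bm2$statistic, 0.09674064381829259, tolerance = 1e-8)
  expect_equal(bm2$p_value, 0.9242457451111548, tolerance = 1e-8)
  expect_equal(bm2$relative_effect, 0.5128205128205128, tolerance = 1e-12)
})

test_that("Brunner-Munzel symmetry, correction, and degenerate handling", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(brunner_munzel(x, x)$relative_effect, 0.5)

  set.seed(2)
  a <- rnorm(10); b <- rnorm(12, 0.7)
  ab <- brunner_munzel(a, b); ba <- brunner_munzel(b, a)
  expect_equal(ab$relative_effect, 1 - ba$relative_effect, tolerance = 1e-12)
  expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)

  # Bonferroni over a planned family of 4 contrasts
  bm4 <- brunner_munzel(a, b, correction_family_size = 4)
  expect_equal(bm4$p_bonferroni, min(1, bm4$p_value * 4))
  fake <- brunner_munzel(c(1, 1, 1), c(1, 1, 1), correction_family_size = 4)
  expect_true(fake$degenerate)
  expect_equal(fake$p_value, 1)

  expect_error(brunner_munzel(1, c(1, 2)), "n >= 2")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(round(bonferroni_threshold(0.05, 9), 4), 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 3), "0, 1")
})

test_that("compact letters code significance patterns correctly", {
  pm <- function(k, vals) {
    m <- matrix(NA_real_, k, k, dimnames = list(letters[1:k], letters[1:k]))
    m[lower.tri(m)] <- vals
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  # no differences: single shared letter
  expect_equal(unname(compact_letters(pm(3, c(0.5, 0.9, 0.2)))),
               c("a", "a", "a"))
  # all different: three distinct letters
  all_sig <- compact_letters(pm(3, c(0.01, 0.001, 0.02)))
  expect_equal(length(unique(all_sig)), 3L)
  expect_true(all(nchar(all_sig) == 1))
  # only pair (1,3) significant: a / ab / b
  mid <- pm(3, c(0.5, 0.01, 0.5))  # lower.tri order: (2,1), (3,1), (3,2)
  expect_equal(unname(compact_letters(mid)), c("a", "ab", "b"))
})

test_that("letter sharing is equivalent to non-significance, exhaustively", {
  share <- function(l1, l2) {
    length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])) > 0
  }
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    m <- matrix(NA_real_, k, k)
    m[lower.tri(m)] <- sample(c(runif(k * (k - 1) / 2 - 1), 0.01))
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    rownames(m) <- colnames(m) <- paste0("g", 1:k)
    lt <- compact_letters(m, alpha = 0.05)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      expect_equal(share(lt[i], lt[j]), m[i, j] >= 0.05,
                   label = sprintf("rep %d pair (%d,%d) p=%.3f letters %s/%s",
                                   rep, i, j, m[i, j], lt[i], lt[j]))
    }
  }
})

test_that("compare_groups assembles omnibus, pairwise and letters", {
  set.seed(5)
  dat <- tibble::tibble(
    group = rep(c("wt", "m1", "m2"), each = 15),
    SI = c(rnorm(15, 0.95, 0.02), rnorm(15, 0.80, 0.04), rnorm(15, 0.78, 0.04))
  )
  gc <- compare_groups(dat, "SI")
  expect_s3_class(gc, "group_comparison")
  expect_lt(gc$omnibus_p, 0.001)
  expect_true(isSymmetric(gc$pairwise))
  expect_false(any(grepl(substr(gc$letters["wt"], 1, 1), gc$letters["m1"])))
  # Brunner-Munzel route applies the pairwise Bonferroni family
  gb <- compare_groups(dat, "SI", method = "brunner_munzel")
  expect_equal(gb$family_size, 3L)
  expect_true(all(gb$pairwise[upper.tri(gb$pairwise)] <= 1))
})
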