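test_that("Benjamini-Hochberg step-up matches an independent hand computation", {
  # independent step-up oracle written from the definition
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
    pmin(1, q_sorted)[order(o)]
  }
  expect_equal(benjamini_hochberg(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  for (rep in 1:10) {
    p <- runif(sample(1:30, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(benjamini_hochberg(c(0.1, 0)), "0, 1")
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "0, 1")
})

test_that("Pearson correlation matches the covariance formula", {
  x <- 1:10
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(11)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  out <- pearson_correlation(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_oracle * sqrt(28 / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_stat), df = 28)
  expect_equal(out$r, r_oracle, tolerance = 1e-12)
  expect_equal(out$p, p_oracle, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
  expect_error(pearson_correlation(1:2, 2:3), "3 complete pairs")
})

test_that("expression filter keeps correlated genes and drops degenerate ones", {
  set.seed(2)
  lr <- matrix(rnorm(30), 3, 10,
               dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:10)))
  expr <- lr
  expr["g1", ] <- 2 * lr["g1", ] + 1        # perfectly linear
  expr["g2", ] <- rnorm(10)                  # uncoupled
  expr["g3", ] <- 5                          # constant: r undefined
  expect_warning(f <- expression_correlation_filter(lr, expr), "dropped")
  expect_true("g1" %in% attr(f, "kept"))
  expect_equal(f$r[f$gene == "g1"], 1)
  expect_false("g3" %in% attr(f, "kept"))
  expect_true(is.na(f$r[f$gene == "g3"]))
})

test_that("differential logR equals the textbook pooled t-test", {
  set.seed(4)
  n1 <- 6; n2 <- 5
  lr <- matrix(rnorm(10 * (n1 + n2)), 10,
               dimnames = list(sprintf("g%02d", 1:10), NULL))
  lr[1, 1:n1] <- lr[1, 1:n1] + 2
  groups <- c(rep("GR", n1), rep("NR", n2))
  out <- differential_logr(lr, groups)
  for (g in rownames(lr)) {
    x <- lr[g, groups == "GR"]; y <- lr[g, groups == "NR"]
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p_oracle <- 2 * pt(-abs(t_oracle), df = n1 + n2 - 2)
    i <- which(out$gene == g)
    expect_equal(out$t_stat[i], t_oracle, tolerance = 1e-10)
    expect_equal(out$p[i], p_oracle, tolerance = 1e-10)
  }
  expect_equal(out$q, benjamini_hochberg(out$p))
  # label swap negates t, preserves p
  swapped <- differential_logr(lr, ifelse(groups == "GR", "NR", "GR"))
  expect_equal(swapped$t_stat, -out$t_stat)
  expect_equal(swapped$p, out$p)
  # identical distributions in both groups -> t = 0, p = 1
  lr_eq <- matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
                  dimnames = list("g1", NULL))
  expect_equal(differential_logr(lr_eq, rep(c("GR", "NR"), each = 3))$t_stat,
               0)
  expect_equal(differential_logr(lr_eq, rep(c("GR", "NR"), each = 3))$p, 1)
})

test_that("differential p-values are uniform under a permutation null", {
  set.seed(19)
  n_genes <- 1000
  lr <- matrix(rnorm(n_genes * 20), n_genes,
               dimnames = list(sprintf("g%04d", 1:n_genes), NULL))
  groups <- sample(rep(c("GR", "NR"), each = 10))
  out <- differential_logr(lr, groups)
  expect_gt(suppressWarnings(ks.test(out$p, "punif"))$p.value, 0.01)
})

test_that("group GII comparison dispatches to t-test and ANOVA correctly", {
  # two groups, equal means -> t = 0
  g2 <- compare_gii_groups(c(1, 2, 3, 1, 2, 3),
                           rep(c("pCR", "non-pCR"), each = 3))
  expect_equal(g2$test, "t")
  expect_equal(g2$statistic, 0)
  # three identical groups -> F = 0, p = 1
  g3 <- compare_gii_groups(rep(c(1, 2, 3), 3), rep(c("GR", "IR", "NR"),
                                                   each = 3))
  expect_equal(g3$test, "anova")
  expect_equal(g3$statistic, 0)
  expect_equal(g3$p, 1)
  expect_error(compare_gii_groups(1:3, c("a", "a", "b")), "2 members")
})

test_that("ANOVA F matches an independent sum-of-squares computation", {
  set.seed(8)
  x <- rnorm(15, mean = rep(c(0, 0.5, 1), each = 5))
  g <- rep(c("GR", "IR", "NR"), each = 5)
  out <- compare_gii_groups(x, g)
  grand <- mean(x)
  ss_b <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_w <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ss_b / 2) / (ss_w / 12)
  expect_equal(out$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(out$p, pf(f_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("significant genes merge into regions by bin adjacency", {
  bins <- make_bins(data.frame(chrom = "1", length = 1e7), 1e6)
  ann <- data.frame(gene = c("a", "b", "c"), chrom = "1",
                    start = c(1e5, 1.2e6, 8.0e6), end = c(2e5, 1.3e6, 8.1e6))
  diff <- data.frame(gene = c("a", "b", "c"), significant = TRUE)
  reg <- significant_regions(diff, ann, bins)
  expect_equal(nrow(reg), 2)  # a+b adjacent bins, c separate
  expect_equal(reg$n_genes, c(2L, 1L))
})
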