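test_that("Mann-Whitney matches its textbook examples", {
  m <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$U, 0)
  expect_equal(m$p, 0.1, tolerance = 1e-12)
  expect_equal(m$method, "exact")
  x <- c(2, 2, 5, 7)
  m2 <- mann_whitney_u(x, x)
  expect_equal(m2$U, length(x)^2 / 2)
  expect_equal(m2$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "myovib_error_empty_sample")
})

test_that("exact Mann-Whitney p equals the enumeration oracle (ties included)", {
  set.seed(11)
  for (n1 in 1:6) {
    for (n2 in 1:6) {
      x <- rnorm(n1)
      y <- rnorm(n2)
      expect_equal(mann_whitney_u(x, y)$p, oracle_mw_p(x, y),
                   tolerance = 1e-12)
    }
  }
  # tied data, including the all-tied baseline group the delta design makes
  xt <- c(-1.2, 0.4, 0.4, 2.0)
  yt <- c(0, 0, 0, 0.4)
  expect_equal(mann_whitney_u(xt, yt)$p, oracle_mw_p(xt, yt),
               tolerance = 1e-12)
  zt <- rep(0, 5)
  wt <- c(-2, -1, 3, 4, 5)
  expect_equal(mann_whitney_u(wt, zt)$p, oracle_mw_p(wt, zt),
               tolerance = 1e-12)
})

test_that("exact p agrees with wilcox.test on tie-free data", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(8)
    y <- rnorm(8)
    expect_equal(mann_whitney_u(x, y)$p,
                 wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("U is symmetric and p is monotone under location shifts", {
  set.seed(13)
  x <- rnorm(7); y <- rnorm(5)
  expect_equal(oracle_u(x, y) + oracle_u(y, x), 35)
  # shifting x up can only strengthen the x-above-y one-sided evidence
  p_at <- function(delta) {
    r <- rank(c(x + delta, y))
    U <- sum(r[1:7]) - 7 * 8 / 2
    U   # larger U = more x-above-y
  }
  shifts <- seq(0, 3, by = 0.5)
  expect_true(all(diff(vapply(shifts, p_at, 0)) >= 0))
})

test_that("normal approximation stays near the exact p at n = 8 + 8", {
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    pe <- mann_whitney_u(x, y, method = "exact")$p
    pn <- mann_whitney_u(x, y, method = "normal")$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("KS statistic equals the brute-force supremum", {
  set.seed(15)
  for (n in c(5, 8, 13)) {
    x <- rnorm(n, 2, 3)
    expect_equal(ks_normality(x, n_mc = 100)$statistic, oracle_ks_stat(x),
                 tolerance = 1e-12)
  }
  # sample at the (i - 0.5)/n normal quantiles: D is 0.5/n up to the exact
  # shift caused by standardizing with the sample sd (sd(q) < 1)
  n <- 16
  q <- qnorm((seq_len(n) - 0.5) / n)
  shift <- max(abs(pnorm(q) - pnorm(q / sd(q))))
  expect_lte(ks_normality(q, n_mc = 100)$statistic, 0.5 / n + shift + 1e-12)
  expect_error(ks_normality(c(1, 2, 3)), class = "myovib_error_small_sample")
  expect_error(ks_normality(rep(1, 8)), class = "myovib_error_zero_variance")
})

test_that("the KS statistic agrees with an independent Lilliefors implementation", {
  skip_if_not_installed("nortest")
  set.seed(19)
  for (n in c(6, 10, 25)) {
    x <- rnorm(n, 3, 2)
    expect_equal(ks_normality(x, n_mc = 100)$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("the Monte-Carlo KS calibration rejects near its nominal level", {
  set.seed(16)
  rejections <- vapply(1:1000, function(i) {
    ks_normality(rnorm(8), n_mc = 10000)$p < 0.05
  }, NA)
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.08)
})

test_that("box-plot summaries follow the 1.5 IQR convention", {
  b <- boxplot_summary(c(1, 2, 3, 4, 5))
  expect_equal(b$Q2, 3)
  expect_equal(b$Q1, 2)
  cst <- boxplot_summary(rep(4, 6))
  expect_equal(cst$Q1, 4); expect_equal(cst$Q3, 4)
  expect_length(cst$outliers, 0)
  x <- c(1, 2, 2.5, 3, 3.5, 4, 50)
  bo <- boxplot_summary(x)
  expect_equal(bo$outliers, 50)
  expect_lte(bo$whisker_high, bo$Q3 + 1.5 * (bo$Q3 - bo$Q1))
  expect_error(boxplot_summary(numeric(0)), class = "myovib_error_empty_sample")
})

test_that("the comparison battery has the designed shape", {
  set.seed(17)
  tab <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                     leg = c("experimental", "control"),
                     stage = vc_stages(),
                     vibration = "on",
                     feature = "delta_stiffness",
                     stringsAsFactors = FALSE)
  tab$value <- ifelse(tab$stage == "T0", 0, rnorm(nrow(tab)))
  res <- compare_all(tab)
  # 6 stages x 2 legs vs baseline + 7 leg-vs-leg = 19 per feature/condition
  expect_equal(nrow(res), 19L)
  expect_equal(sum(res$comparison_kind == "stage_vs_baseline"), 12L)
  expect_equal(sum(res$comparison_kind == "leg_vs_leg"), 7L)
  expect_true(all(res$U <= res$n1 * res$n2, na.rm = TRUE))
  expect_true(all(res$p > 0 & res$p <= 1, na.rm = TRUE))
  expect_identical(res$significant, res$p < 0.05)
})

test_that("cells with too few subjects are marked not computable", {
  tab <- data.frame(subject_id = c("S01", "S01", "S02", "S02"),
                    leg = "experimental",
                    stage = c("T0", "T50-1", "T0", "T50-1"),
                    vibration = "on", feature = "delta_iemg",
                    value = c(0, 1, 0, 2), stringsAsFactors = FALSE)
  res <- compare_all(tab)
  expect_true(all(res$method[res$comparison_kind == "leg_vs_leg"] ==
                    "not_computable"))
  expect_true(any(res$method == "exact"))
})

test_that("Holm correction only ever raises p-values", {
  set.seed(18)
  tab <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                     leg = c("experimental", "control"),
                     stage = vc_stages(), vibration = "on",
                     feature = "delta_stiffness", stringsAsFactors = FALSE)
  tab$value <- ifelse(tab$stage == "T0", 0,
                      rnorm(nrow(tab)) +
                        2 * (tab$leg == "experimental") * (tab$stage != "T0"))
  plain <- compare_all(tab)
  holm <- compare_all(tab, correction = "holm")
  ok <- !is.na(plain$p)
  expect_true(all(holm$p[ok] >= plain$p[ok] - 1e-12))
})
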