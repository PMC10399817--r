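# Nonparametric statistical backbone: Lilliefors-style KS normality screen,
# exact Mann-Whitney U (permutation distribution over midranks, computed by
# dynamic programming -- equivalent to full enumeration of all labelings,
# including tied data), and box-plot summaries.

.myovib_cache <- new.env(parent = emptyenv())

#' Kolmogorov-Smirnov normality screen (Lilliefors-style)
#'
#' One-sample KS statistic against a normal distribution whose mean and sd
#' are estimated from the sample:
#' `D = sup_x |F_emp(x) - Phi((x - mu_hat) / sigma_hat)|`. Because the
#' parameters are estimated, the classical KS null distribution does not
#' apply; the p-value is calibrated by Monte Carlo (standard-normal samples
#' of the same size, default 10000 replicates, deterministic seeding), in
#' the manner of the Lilliefors test. The screen is reported but gates
#' nothing: the downstream comparisons are nonparametric regardless.
#'
#' @param x Numeric sample (n >= 4, nonzero variance).
#' @param n_mc Number of Monte-Carlo calibration replicates.
#' @return A list with `statistic` (D), `p`, `n`, `n_mc`.
#' @export
ks_normality <- function(x, n_mc = 10000) {
  n <- length(x)
  if (n < 4) stop_myovib("small_sample", "ks_normality needs n >= 4")
  s <- stats::sd(x)
  if (s == 0) stop_myovib("zero_variance", "sample has zero variance")
  D <- ks_stat_normal(x)
  null_D <- lilliefors_null(n, n_mc)
  p <- (1 + sum(null_D >= D)) / (n_mc + 1)
  list(statistic = D, p = p, n = n, n_mc = n_mc)
}

# sup over the empirical-CDF jump points of |F_emp - Phi_hat|.
ks_stat_normal <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  P <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - P, P - (seq_len(n) - 1) / n))
}

# Null distribution of D for sample size n, cached; seeded deterministically
# from (n, n_mc) so p-values are reproducible across sessions.
lilliefors_null <- function(n, n_mc) {
  key <- sprintf("lillie_%d_%d", n, n_mc)
  if (!is.null(.myovib_cache[[key]])) return(.myovib_cache[[key]])
  d <- with_seed(substream_seed(195881, key), {
    m <- matrix(stats::rnorm(n * n_mc), nrow = n)
    m <- apply(m, 2L, sort)
    cm <- colMeans(m)
    csd <- sqrt((colSums(m^2) - n * cm^2) / (n - 1))
    P <- stats::pnorm((m - rep(cm, each = n)) / rep(csd, each = n))
    i_over_n <- seq_len(n) / n
    apply(pmax(i_over_n - P, P - (i_over_n - 1 / n)), 2L, max)
  })
  .myovib_cache[[key]] <- d
  d
}

#' Mann-Whitney U test (exact by enumeration, ties supported)
#'
#' Computes `U = sum over pairs of [x_i > y_j] + 0.5 * [x_i = y_j]` and
#' reports `min(U, n1*n2 - U)` as the statistic. For `n1 + n2 <= exact_limit`
#' (default 16, covering the study's 8-vs-8 design) the two-sided p-value is
#' exact: the permutation distribution of the midrank sum over all
#' `choose(n1 + n2, n1)` group labelings — which handles ties correctly — is
#' computed by dynamic programming and `p = min(1, 2 * P(U <= u_min))`.
#' Larger samples use the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param method `"auto"` (exact when affordable), `"exact"`, or
#'   `"normal"`.
#' @param alpha Significance level for the `significant` flag.
#' @param exact_limit Maximum `n1 + n2` for enumeration under `"auto"`.
#' @return A list of class `mw_test` with fields `U`, `p`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal_approx"`), `alpha`, `significant`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal"),
                           alpha = 0.05, exact_limit = 16L) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop_myovib("empty_sample", "both samples must be nonempty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U_x <- W - n1 * (n1 + 1) / 2
  u_min <- min(U_x, n1 * n2 - U_x)
  use_exact <- switch(method,
                      auto = (n1 + n2) <= exact_limit,
                      exact = TRUE,
                      normal = FALSE)
  if (use_exact) {
    p <- mw_exact_p(r, n1, u_min)
    meth <- "exact"
  } else {
    ties <- table(c(x, y))
    N <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U_x - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    meth <- "normal_approx"
  }
  structure(list(U = u_min, p = p, n1 = n1, n2 = n2, method = meth,
                 alpha = alpha, significant = p < alpha),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]%s\n",
              x$U, x$n1, x$n2, x$p, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

# Exact two-sided p for statistic u_min given the pooled midranks.
# The permutation distribution of the x-group rank sum over all
# choose(N, n1) labelings is built by DP over items with integer weights
# 2 * midrank; distributions are cached by the midrank multiset, so repeated
# tests on the same tie pattern (e.g. replicate studies) cost nothing.
mw_exact_p <- function(r, n1, u_min) {
  r2 <- as.integer(round(2 * r))
  counts <- mw_ranksum_distribution(r2, n1)
  # U = W - n1(n1+1)/2 with W the midrank sum; in doubled units:
  w2_min <- round(2 * u_min + n1 * (n1 + 1))
  total <- sum(counts)
  p_one <- sum(counts[seq_len(min(w2_min + 1L, length(counts)))]) / total
  min(1, 2 * p_one)
}

mw_ranksum_distribution <- function(r2, n1) {
  key <- paste0("mw_", n1, "_", paste(sort(r2), collapse = ","))
  if (!is.null(.myovib_cache[[key]])) return(.myovib_cache[[key]])
  S <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # f[j + 1, s + 1] = number of j-subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = S + 1L)
  f[1L, 1L] <- 1
  for (w in r2) {
    jmax <- n1
    for (j in jmax:1L) {
      shifted <- c(rep(0, w), f[j, seq_len(S + 1L - w)])
      f[j + 1L, ] <- f[j + 1L, ] + shifted
    }
  }
  counts <- f[n1 + 1L, ]  # indexed by s = 0..S (doubled-rank sum)
  .myovib_cache[[key]] <- counts
  counts
}

#' Stage-wise comparison battery
#'
#' Reproduces the congestion study's statistical design on a delta table:
#' for every feature and vibration condition present, (a) each
#' non-baseline stage is compared against baseline within each leg, and
#' (b) the experimental and control legs are compared at every stage — all
#' with two-sided Mann-Whitney U tests on per-subject values, with no
#' multiple-testing correction by default (matching the original design;
#' Holm is available behind a flag). Cells with fewer than two subjects are
#' marked not computable and the run continues.
#'
#' @param delta_table A delta table: columns `subject_id`, `leg`, `stage`,
#'   `vibration`, `feature`, `value`.
#' @param alpha Significance level.
#' @param baseline_stage Baseline stage label.
#' @param correction `"none"` (default) or `"holm"` (applied within each
#'   feature x vibration family).
#' @return A `data.frame` with one row per comparison: `comparison_kind`
#'   (`stage_vs_baseline` / `leg_vs_leg`), `feature`, `vibration`, `stage`,
#'   `leg`, `n1`, `n2`, `U`, `p`, `method`, `significant`, `stars`.
#' @export
compare_all <- function(delta_table, alpha = 0.05, baseline_stage = "T0",
                        correction = c("none", "holm")) {
  correction <- match.arg(correction)
  need <- c("subject_id", "leg", "stage", "vibration", "feature", "value")
  if (!all(need %in% names(delta_table)))
    stop_myovib("bad_table", "delta table must have columns: ",
                paste(need, collapse = ", "))
  rows <- list()
  for (feat in unique(delta_table$feature)) {
    for (vib in unique(delta_table$vibration[delta_table$feature == feat])) {
      d <- delta_table[delta_table$feature == feat &
                         delta_table$vibration == vib, ]
      stages <- intersect(vc_stages(), unique(d$stage))
      cell <- function(leg, stage) d$value[d$leg == leg & d$stage == stage]
      one <- function(kind, stage, leg, x, y) {
        if (length(x) < 2L || length(y) < 2L) {
          list(comparison_kind = kind, feature = feat, vibration = vib,
               stage = stage, leg = leg,
               n1 = length(x), n2 = length(y),
               U = NA_real_, p = NA_real_, method = "not_computable",
               significant = NA)
        } else {
          m <- mann_whitney_u(x, y, alpha = alpha)
          list(comparison_kind = kind, feature = feat, vibration = vib,
               stage = stage, leg = leg, n1 = m$n1, n2 = m$n2,
               U = m$U, p = m$p, method = m$method,
               significant = m$significant)
        }
      }
      for (leg in .legs) {
        for (stage in setdiff(stages, baseline_stage)) {
          rows[[length(rows) + 1L]] <-
            one("stage_vs_baseline", stage, leg,
                cell(leg, stage), cell(leg, baseline_stage))
        }
      }
      for (stage in stages) {
        rows[[length(rows) + 1L]] <-
          one("leg_vs_leg", stage, NA_character_,
              cell("experimental", stage), cell("control", stage))
      }
    }
  }
  chr <- function(f) vapply(rows, function(r) as.character(r[[f]]), "")
  num <- function(f) vapply(rows, function(r) as.numeric(r[[f]]), 0)
  res <- data.frame(
    comparison_kind = chr("comparison_kind"), feature = chr("feature"),
    vibration = chr("vibration"), stage = chr("stage"), leg = chr("leg"),
    n1 = as.integer(num("n1")), n2 = as.integer(num("n2")),
    U = num("U"), p = num("p"), method = chr("method"),
    significant = vapply(rows, function(r) as.logical(r[["significant"]]), NA),
    stringsAsFactors = FALSE)
  if (correction == "holm") {
    fam <- interaction(res$feature, res$vibration, drop = TRUE)
    for (f in levels(fam)) {
      i <- fam == f & !is.na(res$p)
      res$p[i] <- stats::p.adjust(res$p[i], method = "holm")
    }
    res$significant <- res$p < alpha
  }
  res$stars <- significance_stars(res$p)
  rownames(res) <- NULL
  res
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Box-plot summary (quartiles, 1.5 IQR whiskers, outliers)
#'
#' Quartiles by linear interpolation between order statistics; the whiskers
#' extend to the most extreme points within `Q3 + 1.5 * (Q3 - Q1)` and
#' `Q1 - 1.5 * (Q3 - Q1)`; points beyond them are outliers — the convention
#' of the congestion study's figures.
#'
#' @param x Numeric sample (nonempty).
#' @return A list with `Q1`, `Q2`, `Q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
boxplot_summary <- function(x) {
  if (length(x) == 0L) stop_myovib("empty_sample", "empty sample")
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  hi_fence <- q[3] + 1.5 * iqr
  lo_fence <- q[1] - 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  list(Q1 = q[1], Q2 = q[2], Q3 = q[3],
       whisker_low = min(x[inside]),
       whisker_high = max(x[inside]),
       outliers = x[!inside],
       n = length(x))
}

#' Box-plot summaries for every cell of a delta table
#'
#' @param delta_table A delta table (see [compare_all()]).
#' @return A `data.frame` with one row per feature x vibration x leg x
#'   stage cell: quartiles, whiskers and outlier count.
#' @export
boxplot_summaries <- function(delta_table) {
  by <- interaction(delta_table$feature, delta_table$vibration,
                    delta_table$leg, delta_table$stage, drop = TRUE)
  out <- lapply(split(delta_table, by), function(g) {
    b <- boxplot_summary(g$value)
    data.frame(feature = g$feature[1], vibration = g$vibration[1],
               leg = g$leg[1], stage = g$stage[1],
               Q1 = b$Q1, Q2 = b$Q2, Q3 = b$Q3,
               whisker_low = b$whisker_low, whisker_high = b$whisker_high,
               n_outliers = length(b$outliers), n = b$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$feature, res$vibration, res$leg,
            match(res$stage, vc_stages())), , drop = FALSE]
}
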