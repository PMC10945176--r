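# brute-force oracles kept deliberately independent of the implementations
pair_auc_oracle <- function(scores, truths) {
  pos <- scores[truths == 1]
  neg <- scores[truths == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

test_that("auc matches perfect, reversed and brute-force pair counting", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  set.seed(10)
  for (i in 1:5) {
    s <- sample(seq(0, 1, by = 0.1), 50, replace = TRUE)  # ties included
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), pair_auc_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "classes")
})

test_that("auc is invariant under strictly monotone score transforms", {
  set.seed(11)
  s <- runif(100)
  y <- rbinom(100, 1, 0.4)
  a0 <- auc(s, y)
  expect_equal(auc(plogis(5 * s - 2), y), a0)
  expect_equal(auc(s^3, y), a0)
})

test_that("bce matches closed forms and direct summation", {
  expect_lt(bce(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_equal(bce(rep(0.5, 8), rbinom(8, 1, 0.5)), log(2), tolerance = 1e-12)
  set.seed(12)
  s <- runif(20)
  y <- rbinom(20, 1, 0.5)
  direct <- 0
  for (i in 1:20) direct <- direct - (y[i] * log(s[i]) +
                                      (1 - y[i]) * log(1 - s[i]))
  expect_equal(bce(s, y), direct / 20, tolerance = 1e-9)
})

test_that("ece matches closed forms, bin summation and the calibrated limit", {
  expect_equal(ece(rep(1, 10), rep(1, 10)), 0)
  expect_equal(ece(rep(0.9, 10), rep(0, 10)), 0.9)
  set.seed(13)
  s <- runif(200)
  y <- rbinom(200, 1, s)
  # direct bin summation oracle
  bins <- pmin(pmax(ceiling(s * 10), 1), 10)
  direct <- 0
  for (b in 1:10) {
    in_b <- bins == b
    if (!any(in_b)) next
    direct <- direct + sum(in_b) / 200 * abs(mean(y[in_b]) - mean(s[in_b]))
  }
  expect_equal(ece(s, y), direct, tolerance = 1e-12)
  # calibrated by construction -> small ECE
  set.seed(14)
  s <- runif(1e5)
  y <- rbinom(1e5, 1, s)
  expect_lt(ece(s, y), 0.02)
  # scores equal to their bin's empirical accuracy -> ECE exactly 0
  s0 <- c(rep(0.25, 4), rep(0.75, 4))
  y0 <- c(1, 0, 0, 0, 1, 1, 1, 0)
  expect_equal(ece(s0, y0), 0)
})

test_that("error rate and precision follow confusion-matrix arithmetic", {
  # TP=3, FP=1, FN=2, TN=4 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.3, 0.1, 0.15, 0.05, 0.25)
  truths <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  expect_equal(error_rate(scores, truths, 0.5), 0.3)
  expect_equal(precision(scores, truths, 0.5), 0.75)
  expect_equal(error_rate(c(0.9, 0.1), c(1, 0), 0.5), 0)
  expect_equal(precision(c(0.9, 0.1), c(1, 0), 0.5), 1)
  # threshold 0 -> everything predicted positive -> precision = prevalence
  expect_equal(precision(scores, truths, 0), mean(truths))
  expect_warning(p <- precision(c(0.1, 0.2), c(0, 1), 0.9), "undefined")
  expect_true(is.na(p))
})

test_that("group metrics use shared thresholds and match per-group oracles", {
  set.seed(15)
  n <- 60
  g <- rep(c("a", "b"), each = n)
  s <- c(runif(n), pmin(runif(n) + 0.3, 1))
  y <- rbinom(2 * n, 1, 0.5)
  ss <- score_set(matrix(s, ncol = 1, dimnames = list(NULL, "lab")),
                  matrix(y, ncol = 1), groups = g)
  gm <- group_metrics(ss, thresholds = c(lab = 0.5))
  for (grp in c("a", "b")) {
    keep <- g == grp
    expect_equal(gm$auc[gm$group == grp], pair_auc_oracle(s[keep], y[keep]),
                 tolerance = 1e-12)
    expect_equal(gm$error_rate[gm$group == grp],
                 mean((s[keep] >= 0.5) != y[keep]))
  }
  # shifted scores change BCE between groups
  expect_false(isTRUE(all.equal(gm$bce[1], gm$bce[2])))
})

test_that("fairness gaps behave like a range statistic", {
  expect_equal(fairness_gap(c(0.80, 0.80, 0.80)), 0)
  expect_equal(fairness_gap(c(0.937, 0.954, 0.950)), 0.017)
  v <- c(0.3, 0.9, 0.5)
  expect_equal(fairness_gap(v), fairness_gap(rev(v)))
  expect_equal(fairness_gap(c(v, 0.9)), fairness_gap(v))
  expect_gte(fairness_gap(stats::runif(4)), 0)
  expect_error(fairness_gap(c(0.5, NA)), "finite")
  expect_equal(macro_average_gap(c(0.1, 0.3)), 0.2)
  expect_equal(fairness_gap(c(0, 1, 0.5), method = "mean_pairwise"),
               mean(c(1, 0.5, 0.5)))
})

test_that("bootstrap CIs are deterministic, degenerate on constants and near analytic width", {
  set.seed(16)
  n <- 200
  x <- rnorm(n, mean = 2, sd = 1.5)
  ss <- score_set(matrix(plogis(x), ncol = 1), matrix(rbinom(n, 1, 0.5)))
  ss$x <- rep(x, each = 1)
  const_stat <- function(d) 1.23
  r0 <- bootstrap_ci(ss, const_stat, bootstrap_config(iterations = 100))
  expect_equal(r0$upper - r0$lower, 0)
  mean_stat <- function(d) mean(d$x)
  cfg <- bootstrap_config(iterations = 1000, seed = 2021)
  r1 <- bootstrap_ci(ss, mean_stat, cfg)
  r2 <- bootstrap_ci(ss, mean_stat, cfg)
  expect_identical(r1, r2)
  analytic_width <- 2 * stats::qnorm(0.975) * stats::sd(x) / sqrt(n)
  expect_lt(abs((r1$upper - r1$lower) - analytic_width) / analytic_width, 0.2)
})

test_that("bootstrap mean converges to the point statistic as B grows", {
  set.seed(17)
  n <- 150
  s <- runif(n)
  y <- rbinom(n, 1, s)
  ss <- score_set(matrix(s, ncol = 1), matrix(y, ncol = 1))
  stat <- function(d) auc(d$score, d$truth)
  point <- stat(ss)
  errs <- vapply(c(10, 100, 1000), function(B) {
    abs(bootstrap_ci(ss, stat, bootstrap_config(iterations = B))$boot_mean -
          point)
  }, numeric(1))
  expect_lt(errs[3], 0.02)
})

test_that("gap_report assembles gaps, macro averages and CIs coherently", {
  set.seed(18)
  n <- 80
  g <- sample(c("a", "b", "c"), n, replace = TRUE)
  s <- cbind(l1 = runif(n), l2 = runif(n))
  y <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  ss <- score_set(s, y, groups = g)
  rep <- gap_report(ss, thresholds = 0.5,
                    boot = bootstrap_config(iterations = 50))
  expect_s3_class(rep, "gap_report")
  expect_true(all(tidy(rep)$gap >= 0, na.rm = TRUE))
  expect_equal(nrow(glance(rep)), 5)
  m <- glance(rep)
  gaps <- tidy(rep)
  for (met in m$metric) {
    expect_equal(m$macro_gap[m$metric == met],
                 mean(gaps$gap[gaps$metric == met], na.rm = TRUE))
  }
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("roc curves integrate back to the auc and report the cutoff point", {
  perfect <- score_set(matrix(c(0.9, 0.8, 0.2, 0.1), ncol = 1),
                       matrix(c(1, 1, 0, 0), ncol = 1),
                       groups = rep("g", 4))
  rr <- roc_with_cutoff(perfect, thresholds = 0.5)
  expect_equal(rr$cutoffs$tpr, 1)
  expect_equal(rr$cutoffs$fpr, 0)
  rr0 <- roc_with_cutoff(perfect, thresholds = 0)
  expect_equal(rr0$cutoffs$tpr, 1)
  expect_equal(rr0$cutoffs$fpr, 1)
  set.seed(19)
  s <- sample(seq(0, 1, 0.05), 120, replace = TRUE)
  y <- rbinom(120, 1, pmin(s + 0.2, 1))
  ss <- score_set(matrix(s, ncol = 1), matrix(y, ncol = 1),
                  groups = rep("g", 120))
  rc <- roc_with_cutoff(ss, thresholds = 0.5)
  cur <- rc$curves
  trap <- sum(diff(cur$fpr) * (head(cur$tpr, -1) + tail(cur$tpr, -1)) / 2)
  expect_equal(trap, auc(s, y), tolerance = 1e-9)
})
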