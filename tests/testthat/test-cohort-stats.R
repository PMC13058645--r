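test_that("one-way ANOVA matches the textbook formula and flags degeneracy", {
  df0 <- data.frame(y = rep(c(1, 2), 3), group = rep(c("a", "b", "c"), each = 2))
  expect_equal(anova_oneway(df0, "y")$F, 0)

  set.seed(11)
  dfr <- data.frame(y = rnorm(60), group = rep(c("HC", "SUB", "CHR"), 20))
  got <- anova_oneway(dfr, "y")
  ref <- anova_oneway_hand(dfr$y, dfr$group)
  expect_equal(got$F, ref$F, tolerance = 1e-10)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
  expect_equal(c(got$df1, got$df2), c(ref$df1, ref$df2))

  dg <- data.frame(y = rep(5, 9), group = rep(c("a", "b", "c"), 3))
  expect_true(anova_oneway(dg, "y")$degenerate)
  expect_error(anova_oneway(data.frame(y = 1:3, group = c("a", "a", "b")),
                            "y"),
               class = "dyadsync_input_error")
})

simulate_stats_table <- function(n = 90, icc_sd = 0.05, chr_effect = -0.06,
                                 seed = 1) {
  withr::with_seed(seed, {
    g <- factor(rep(c("HC", "SUB", "CHR"), length.out = n),
                levels = c("HC", "SUB", "CHR"))
    aid <- sample(sprintf("A%02d", 1:12), n, replace = TRUE)
    u <- stats::setNames(rnorm(12, sd = icc_sd), sprintf("A%02d", 1:12))
    tibble::tibble(
      dyad_id = sprintf("D%03d", 1:n),
      group = g,
      participant_sex = sample(c("F", "M"), n, TRUE),
      assessor_sex = sample(c("F", "M"), n, TRUE),
      assessor_id = aid,
      strength = 1.2 + ifelse(g == "CHR", chr_effect, 0) + u[aid] +
        rnorm(n, sd = 0.07),
      delay_s = rnorm(n, sd = 0.3)
    )
  })
}

test_that("the mixed model recovers fixed effects, ICC and handles singular fits", {
  tab <- simulate_stats_table(n = 240, icc_sd = 0.08, seed = 2)
  m <- fit_strength_model(tab, "strength")
  expect_s3_class(m, "synchrony_mixed_model")
  expect_true(all(c("(Intercept)", "groupSUB", "groupCHR") %in% m$fixed$term))
  expect_lt(m$fixed$estimate[m$fixed$term == "groupCHR"], 0)
  expect_gte(m$icc, 0)
  expect_lte(m$icc, 1)
  expect_equal(m$icc, m$var_assessor / (m$var_assessor + m$var_residual))
  # confidence limits bracket the estimates
  expect_true(all(m$fixed$conf.low < m$fixed$estimate &
                    m$fixed$estimate < m$fixed$conf.high))

  gl <- glance(m)
  expect_equal(gl$icc, m$icc)
  td <- tidy(m)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high",
                     "df", "statistic", "p.value"))

  expect_error(fit_strength_model(tab[tab$assessor_id == tab$assessor_id[1], ],
                                  "strength"),
               class = "dyadsync_input_error")
})

test_that("post hoc group contrasts cover all pairs with FDR-adjusted p", {
  tab <- simulate_stats_table(n = 150, seed = 3)
  m <- fit_strength_model(tab, "strength")
  ph <- posthoc_group_contrasts(m)
  expect_equal(nrow(ph), 3L)
  expect_setequal(ph$contrast, c("HC - SUB", "HC - CHR", "SUB - CHR"))
  expect_true(all(ph$p.adjusted >= ph$p.value - 1e-12))
})

test_that("two-way ANOVA matches textbook sums of squares on balanced data", {
  set.seed(4)
  cells <- expand.grid(group = c("HC", "SUB", "CHR"),
                       dyad_type = c("MM", "FF", "MF", "FM"))
  df <- cells[rep(1:12, each = 4), ]
  df$y <- rnorm(48) + ifelse(df$group == "CHR", -0.5, 0)
  got <- anova_twoway(df, "y")
  ref <- anova_twoway_hand(df$y, df$group, df$dyad_type)
  expect_equal(got$sumsq, ref$ss, tolerance = 1e-10)
  expect_equal(got$statistic, ref$F, tolerance = 1e-10)
  expect_equal(got$p.value, ref$p, tolerance = 1e-10)
  expect_equal(got$ges, ref$ges, tolerance = 1e-10)
  expect_equal(got$term, c("group", "dyad_type", "group:dyad_type"))

  single <- df[df$group == "HC" & df$dyad_type == "MM", ]
  expect_error(anova_twoway(single, "y"), class = "dyadsync_input_error")
})

test_that("empty crossing cells are reported but estimable terms survive", {
  set.seed(5)
  df <- expand.grid(group = c("HC", "SUB", "CHR"),
                    dyad_type = c("MM", "FF", "MF", "FM"))
  df <- df[rep(1:12, each = 3), ]
  df <- df[!(df$group == "CHR" & df$dyad_type == "FM"), ]
  df$y <- rnorm(nrow(df))
  expect_message(res <- anova_twoway(df, "y"), "empty")
  expect_true(all(is.finite(res$statistic[res$term %in%
                                            c("group", "dyad_type")])))
})

test_that("Benjamini-Hochberg adjustment equals the brute-force step-up", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "dyadsync_input_error")
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in sorted order
  }
})

test_that("score correlations use pairwise deletion, flags, and one FDR family", {
  tab <- tibble::tibble(
    group = rep(c("CHR", "SUB", "HC"), each = 10),
    delay_s = c(seq(0, 0.9, length.out = 10), rnorm(20, sd = 0.2)),
    strength = rnorm(30, 1.2, 0.1),
    n1 = NA_real_, flat = 1
  )
  tab$n1 <- 2 * tab$delay_s + c(rep(0, 10), rnorm(20, sd = 0.1))
  tab$n1[12] <- NA
  res <- pearson_with_fdr(tab, "delay_s", c("n1", "flat"), groups = "CHR")
  expect_equal(res$r[res$score == "n1"], 1, tolerance = 1e-12)
  expect_equal(res$flag[res$score == "flat"], "constant")
  expect_true(is.na(res$p_adjusted[res$score == "flat"]))

  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  tab2 <- tibble::tibble(group = "CHR", strength = x, s1 = y)
  r2 <- pearson_with_fdr(tab2, "strength", "s1")
  expect_equal(r2$r, pearson_hand(x, y), tolerance = 1e-12)

  few <- tibble::tibble(group = "CHR", strength = c(1, 2, 3),
                        s1 = c(1, NA, 2))
  expect_equal(pearson_with_fdr(few, "strength", "s1")$flag, "too_few")
})

test_that("the CHR fixed-effect test is calibrated under null cohorts", {
  rejections <- vapply(1:300, function(r) {
    tab <- simulate_stats_table(n = 90, icc_sd = 0.04, chr_effect = 0,
                                seed = 700 + r)
    m <- suppressMessages(fit_strength_model(tab, "strength"))
    m$fixed$p.value[m$fixed$term == "groupCHR"] < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.08)
})

test_that("two-way ANOVA p values are calibrated on balanced null data", {
  set.seed(13)
  cells <- expand.grid(group = c("HC", "SUB", "CHR"),
                       dyad_type = c("MM", "FF", "MF", "FM"))
  pvals <- t(vapply(1:200, function(r) {
    df <- cells[rep(1:12, each = 3), ]
    df$y <- rnorm(36)
    anova_twoway(df, "y")$p.value
  }, numeric(3)))
  for (j in 1:3) {
    expect_gte(mean(pvals[, j] < 0.05), 0.01)
    expect_lte(mean(pvals[, j] < 0.05), 0.10)
    expect_gt(mean(pvals[, j]), 0.4)  # roughly uniform, not skewed
  }
})
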