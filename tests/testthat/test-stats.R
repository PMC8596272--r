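# Inference layer: deltas, contrasts, Wilks MANOVA, corrected alpha,
# assumption checks, post-hoc machinery.

# tiny hand-made HFD table: 2 subjects x (rest + 2 stimuli) x 1 band x
# 4 lateral channels
tiny_table <- function(stim_offset = 0.1) {
  chans <- c("C3", "C4", "T3", "T4")
  hemi <- c("left", "right", "left", "right")
  locus <- c(5L, 5L, 4L, 4L)
  rows <- expand.grid(subject = c("S1", "S2"),
                      state = c("rest", "cough", "laughter"),
                      channel = chans, stringsAsFactors = FALSE)
  rows$band <- "broadband"
  rows$group <- ifelse(rows$subject == "S1", "control", "severe_dai")
  rows$hemisphere <- hemi[match(rows$channel, chans)]
  rows$locus <- locus[match(rows$channel, chans)]
  rows$hfd <- 1.5 + ifelse(rows$state == "rest", 0, stim_offset) +
    0.01 * as.integer(factor(rows$subject))
  rows
}

test_that("rest_difference consumes rest and preserves cardinality", {
  tab <- tiny_table(0)
  d0 <- rest_difference(tab)
  expect_true(all(d0$delta_hfd == 0))
  tab2 <- tiny_table(0.07)
  d <- rest_difference(tab2)
  expect_identical(nrow(d), nrow(tab2[tab2$state != "rest", ]))
  expect_false("rest" %in% d$stimulus)
  expect_true(all(abs(d$delta_hfd - 0.07) < 1e-12))
  # each (subject, band, channel) keeps exactly its stimulus count
  expect_true(all(table(d$subject, d$channel) == 2L))
  tab3 <- tab2[!(tab2$state == "rest" & tab2$subject == "S1" &
                   tab2$channel == "C3"), ]
  expect_error(rest_difference(tab3), class = "fe_data_error")
})

test_that("hemisphere contrast is a left-minus-right mean", {
  tab <- tiny_table(0.1)
  # symmetric table -> zero contrast
  expect_true(all(abs(hemisphere_contrast(tab)$contrast) < 1e-12))
  tab$hfd[tab$hemisphere == "left"] <- tab$hfd[tab$hemisphere == "left"] + 0.02
  hc <- hemisphere_contrast(tab)
  expect_true(all(abs(hc$contrast - 0.02) < 1e-12))
  # single subject: contrast equals that subject's pair-mean difference
  one <- tab[tab$subject == "S1" & tab$state == "rest", ]
  hc1 <- hemisphere_contrast(one)
  expect_equal(hc1$contrast,
               mean(one$hfd[one$hemisphere == "left"]) -
                 mean(one$hfd[one$hemisphere == "right"]))
  bad <- tab; bad$hemisphere <- NULL
  expect_error(hemisphere_contrast(bad), class = "fe_data_error")
})

test_that("Wilks lambda: closed forms and brute-force agreement", {
  set.seed(31)
  # single response, 2 groups: equals one-way ANOVA
  y <- rnorm(24); g <- rep(c("a", "b"), 12)
  mv <- wilks_manova(matrix(y), g)
  f_aov <- anova(stats::lm(y ~ g))$F[1L]
  expect_equal(mv$f_stat, f_aov, tolerance = 1e-12)
  expect_equal(mv$wilks_lambda, 1 / (1 + f_aov * 1 / 22), tolerance = 1e-12)
  # identical group means: lambda = 1, F = 0
  A <- matrix(rnorm(20), 10, 2)
  mv0 <- wilks_manova(rbind(A, A), rep(c("a", "b"), each = 10))
  expect_equal(mv0$wilks_lambda, 1, tolerance = 1e-12)
  expect_equal(mv0$f_stat, 0, tolerance = 1e-12)
  # 3 groups, 4 responses: determinant-ratio and eigenvalue oracles
  Y <- matrix(rnorm(120), 30, 4)
  g3 <- rep(c("a", "b", "c"), 10)
  mv3 <- wilks_manova(Y, g3)
  or <- oracle_wilks(Y, g3)
  expect_lt(abs(mv3$wilks_lambda - or$det_ratio), 1e-10)
  expect_lt(abs(mv3$wilks_lambda - or$eigen), 1e-10)
  expect_true(mv3$partial_eta_sq >= 0 && mv3$partial_eta_sq < 1)
  # cross-check F and p against stats::manova
  sm <- summary(stats::manova(Y ~ factor(g3)), test = "Wilks")$stats
  expect_equal(mv3$f_stat, unname(sm[1L, 3L]), tolerance = 1e-10)
  expect_equal(mv3$p, unname(sm[1L, 6L]), tolerance = 1e-10)
})

test_that("two-factor Wilks matches stats::manova term by term", {
  set.seed(77)
  g <- rep(c("a", "b", "c"), each = 20)
  s <- rep(rep(c("x", "y"), each = 10), 3)
  Y <- matrix(rnorm(180), 60, 3)
  Y[g == "c", ] <- Y[g == "c", ] + 0.8
  res <- wilks_manova(Y, g, s)
  sm <- summary(stats::manova(Y ~ factor(g) * factor(s)),
                test = "Wilks")$stats
  expect_equal(res$group$wilks_lambda, unname(sm[1L, 2L]), tolerance = 1e-10)
  expect_equal(res$stimulus$wilks_lambda, unname(sm[2L, 2L]),
               tolerance = 1e-10)
  expect_equal(res$`group:stimulus`$wilks_lambda, unname(sm[3L, 2L]),
               tolerance = 1e-10)
  expect_equal(res$group$p, unname(sm[1L, 6L]), tolerance = 1e-9)
})

test_that("rank and shape errors are classed", {
  Y <- cbind(1:10, (1:10) * 2)   # exactly collinear responses
  expect_error(wilks_manova(Y, rep(c("a", "b"), 5)), class = "fe_rank_error")
  expect_error(wilks_manova(matrix(rnorm(10)), rep("a", 10)),
               class = "fe_param_error")
  expect_error(wilks_manova(matrix(rnorm(8), 4, 2), rep(c("a", "b"), 2)),
               class = "fe_param_error")   # n <= p + g
})

test_that("corrected alpha reproduces the printed thresholds", {
  expect_equal(as.numeric(corrected_alpha(0.05, 3L)), 0.017)
  expect_equal(as.numeric(corrected_alpha(0.05, 18L)), 0.003)
  expect_equal(as.numeric(corrected_alpha(0.05, 162L)), 0.0003)
  expect_equal(as.numeric(corrected_alpha(0.3, 1L)), 0.3)
  expect_equal(attr(corrected_alpha(0.05, 3L), "exact"), 0.05 / 3)
  expect_error(corrected_alpha(0.05, 0L), class = "fe_param_error")
  expect_error(corrected_alpha(1.2, 3L), class = "fe_param_error")
})

test_that("Levene test matches its ANOVA definition and detects spread", {
  g1 <- c(1, 2, 3, 4); same <- list(a = g1, b = g1, c = g1)
  lv0 <- levene_test(same)
  expect_equal(lv0$statistic, 0)
  expect_equal(lv0$p, 1)
  set.seed(9)
  x <- list(a = rnorm(40), b = rnorm(45, sd = 1.4), c = rnorm(38))
  lv <- levene_test(x)
  z <- unlist(lapply(x, function(v) abs(v - mean(v))))
  gg <- factor(rep(names(x), lengths(x)))
  f_or <- anova(stats::lm(z ~ gg))$F[1L]
  expect_lt(abs(lv$statistic - f_or), 1e-10)
  # power: variance ratio 9 at n = 100 is essentially always detected
  set.seed(12)
  big <- list(a = rnorm(100), b = rnorm(100, sd = 3))
  expect_lt(levene_test(big)$p, 0.01)
  expect_lt(levene_test(big, center = "median")$p, 0.01)
  expect_error(levene_test(list(a = 1, b = c(1, 2))),
               class = "fe_param_error")
})

test_that("Lilliefors-corrected KS: level, power, statistic range", {
  lev <- vapply(1:60, function(i) {
    set.seed(i); ks_normality(rnorm(1000))$p > 0.05
  }, logical(1))
  expect_gte(mean(lev), 0.9)
  pow <- vapply(1:30, function(i) {
    set.seed(i); ks_normality(rexp(200))$p < 0.05
  }, logical(1))
  expect_gte(mean(pow), 0.9)
  set.seed(2)
  d <- ks_normality(rnorm(50))$statistic
  expect_true(d >= 0 && d <= 1)
  expect_error(ks_normality(rep(1, 20)), class = "fe_degenerate_error")
  expect_error(ks_normality(rnorm(4)), class = "fe_param_error")
})

test_that("post-hoc families agree with their references", {
  set.seed(14)
  x <- list(a = rnorm(10), b = rnorm(12) + 0.5, c = rnorm(11))
  # Tukey HSD vs base TukeyHSD
  ph <- posthoc(x, "tukey")
  df <- data.frame(v = unlist(x), g = factor(rep(names(x), lengths(x))))
  th <- TukeyHSD(stats::aov(v ~ g, df))$g
  expect_equal(ph$pairs$p_adjusted,
               unname(th[c("b-a", "c-a", "c-b"), "p adj"]), tolerance = 1e-8)
  # Games-Howell converges to Tukey for equal variances and n
  set.seed(15)
  xl <- list(a = rnorm(400), b = rnorm(400), c = rnorm(400))
  expect_lt(max(abs(posthoc(xl, "games_howell")$pairs$p_adjusted -
                      posthoc(xl, "tukey")$pairs$p_adjusted)), 0.01)
  # Dunnett with a single comparison reduces to the two-sided pooled t-test
  set.seed(16)
  x2 <- list(ctrl = rnorm(15), trt = rnorm(15) + 0.6)
  d <- posthoc(x2, "dunnett", control = "ctrl", seed = 4L)
  tt <- stats::t.test(x2$trt, x2$ctrl, var.equal = TRUE)
  expect_lt(abs(d$pairs$p_adjusted - tt$p.value), 0.01)
  expect_error(posthoc(x2, "dunnett"), class = "fe_param_error")
  # identical groups: all adjusted p = 1
  xi <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  for (m in c("tukey", "games_howell", "bonferroni_t")) {
    expect_true(all(posthoc(xi, m)$pairs$p_adjusted > 0.999))
  }
})

test_that("post-hoc p-values are invariant to group relabeling", {
  set.seed(18)
  x <- list(a = rnorm(9), b = rnorm(14) + 1, c = rnorm(11) - 0.3)
  key <- function(ph) {
    p <- ph$pairs
    id <- apply(cbind(p$group_a, p$group_b), 1L,
                function(r) paste(sort(r), collapse = "|"))
    stats::setNames(p$p_adjusted, id)[order(id)]
  }
  for (m in c("tukey", "games_howell", "bonferroni_t")) {
    expect_equal(key(posthoc(x, m)), key(posthoc(rev(x), m)),
                 tolerance = 1e-12)
  }
  d1 <- posthoc(x, "dunnett", control = "a", seed = 2L)
  d2 <- posthoc(x[c(2, 1, 3)], "dunnett", control = "a", seed = 2L)
  expect_equal(key(d1), key(d2), tolerance = 0.01)
})
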