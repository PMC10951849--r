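make_long <- function(y_mat, groups, conds = c("maintain", "reappraise")) {
  n <- nrow(y_mat)
  data.frame(participant = rep(sprintf("p%02d", seq_len(n)), 2),
             group = rep(groups, 2),
             condition = rep(conds, each = n),
             value = c(y_mat[, 1], y_mat[, 2]))
}

test_that("split-plot ANOVA matches a hand-worked example and aov()", {
  # frozen textbook-style dataset: 4 participants per group, 2 conditions
  y <- rbind(c(10, 14), c(12, 18), c(11, 15), c(13, 17),   # group g1
             c(20, 21), c(22, 22), c(21, 23), c(19, 20))   # group g2
  g <- rep(c("g1", "g2"), each = 4)
  res <- mixed_anova_2x2(make_long(y, g))

  # independent oracle: base R aov with an Error stratum
  df <- make_long(y, g)
  fit <- aov(value ~ group * condition + Error(participant), data = df)
  s <- summary(fit)
  bet <- s[["Error: participant"]][[1]]
  wit <- s[["Error: Within"]][[1]]
  expect_equal(res$table$F[res$table$effect == "group"],
               bet["group", "F value"], tolerance = 1e-10)
  expect_equal(res$table$F[res$table$effect == "condition"],
               wit["condition", "F value"], tolerance = 1e-10)
  expect_equal(res$table$F[res$table$effect == "group:condition"],
               wit["group:condition", "F value"], tolerance = 1e-10)
  expect_equal(res$table$df2, c(6L, 6L, 6L))

  # sums of squares partition the total exactly
  ss <- res$sums_of_squares
  expect_lt(abs(ss["total"] - (ss["group"] + ss["subj_within"] +
                                 ss["condition"] + ss["interaction"] +
                                 ss["residual"])) / ss["total"], 1e-10)

  # the interaction here is significant -> Bonferroni simple effects present
  expect_false(is.null(res$simple_effects))
  expect_equal(nrow(res$simple_effects), 2)
  d1 <- y[1:4, 2] - y[1:4, 1]
  tt <- t.test(d1)
  i <- which(res$simple_effects$group == "g1")
  expect_equal(res$simple_effects$t[i], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$simple_effects$p_adjusted[i],
               min(1, 2 * tt$p.value), tolerance = 1e-10)
})

test_that("ANOVA is invariant to participant order and degenerate data give F = 0", {
  set.seed(6)
  y <- matrix(rnorm(20), 10)
  g <- rep(c("a", "b"), each = 5)
  d1 <- make_long(y, g)
  perm <- sample(nrow(d1))
  r1 <- mixed_anova_2x2(d1)
  r2 <- mixed_anova_2x2(d1[perm, ])
  expect_equal(r1$table, r2$table, tolerance = 1e-12)

  flat <- make_long(matrix(5, 6, 2), rep(c("a", "b"), each = 3))
  r0 <- mixed_anova_2x2(flat)
  expect_equal(r0$table$F, c(0, 0, 0))

  # a participant missing one condition is excluded with a warning
  d_miss <- d1[-1, ]
  expect_warning(rm_ <- mixed_anova_2x2(d_miss), "excluded")
  expect_equal(rm_$excluded, "p01")
})

test_that("theta regression recovers a planted slope and flags collinearity", {
  set.seed(7)
  n <- 24
  erq_r <- round(rtruncnorm(n, 21, 8, 10, 42))
  erq_s <- round(rtruncnorm(n, 15, 5, 4, 28))
  rd <- rnorm(n, -16, 10)
  theta <- 0.02 * erq_r + rnorm(n, 0, 1e-8)
  reg <- theta_regression(theta, erq_r, erq_s, rd)
  est <- reg$coefficients$estimate[reg$coefficients$term == "erq_r"]
  expect_equal(est, 0.02, tolerance = 1e-6)
  expect_equal(reg$df2, n - 4)
  expect_gte(reg$r_squared, 0.999)
  # residuals orthogonal to the design
  X <- cbind(1, erq_r, erq_s, rd)
  expect_lt(max(abs(t(X) %*% residuals(reg$fit))) / n, 1e-6)
  # duplicated predictor -> collinearity error
  expect_error(theta_regression(theta, erq_r, erq_r, rd), "collinear")
})

test_that("regression type-I error with Bonferroni stays at or below nominal", {
  hits <- matrix(FALSE, 200, 3)
  for (s in 1:200) {
    set.seed(1000 + s)
    n <- 24
    theta <- rnorm(n)
    reg <- theta_regression(theta, rnorm(n), rnorm(n), rnorm(n))
    hits[s, ] <- reg$coefficients$p_adjusted[-1] < 0.05
  }
  rate <- colMeans(hits)
  # Bonferroni over three predictors: per-predictor adjusted rate <= 5%
  # plus 3-sigma binomial slack for 200 simulations
  expect_true(all(rate <= 0.05 + 3 * sqrt(0.05 * 0.95 / 200)))
})
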