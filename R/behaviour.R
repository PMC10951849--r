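## Behavioural and questionnaire statistics: mixed (split-plot) two-way
## ANOVA with Bonferroni simple effects, and the multiple regression
## predicting regulation-associated theta activity.

#' Mixed-model (split-plot) 2 x 2 ANOVA
#'
#' Between-participant factor `group`, within-participant factor
#' `condition` (two levels each). Reports the classical split-plot
#' decomposition: group against the between-participant error, condition
#' and group x condition against the within-participant error. When the
#' interaction is significant, Bonferroni-corrected simple effects (paired
#' t of condition within each group) are reported; otherwise main effects
#' are the focus, matching the usual decision rule.
#'
#' @param data data.frame with columns `participant`, `group`, `condition`,
#'   `value`; participants missing a condition value are excluded with a
#'   warning
#' @param alpha significance level driving the simple-effects decision
#' @return object of class `anova_result` with `table` (F, df, p per
#'   effect), `simple_effects` (or NULL), `excluded`
#' @export
mixed_anova_2x2 <- function(data, alpha = 0.05) {
  stopifnot(all(c("participant", "group", "condition", "value") %in% names(data)))
  data$participant <- as.character(data$participant)
  data$group <- as.character(data$group)
  data$condition <- as.character(data$condition)
  conds <- sort(unique(data$condition))
  groups <- sort(unique(data$group))
  if (length(conds) != 2 || length(groups) != 2)
    stop("exactly two conditions and two groups required")

  counts <- table(data$participant)
  complete <- names(counts)[counts == 2]
  excluded <- setdiff(unique(data$participant), complete)
  if (length(excluded)) {
    warning(length(excluded), " participant(s) excluded (missing a condition value): ",
            paste(excluded, collapse = ", "))
    data <- data[data$participant %in% complete, , drop = FALSE]
  }
  if (anyNA(data$value)) {
    bad <- unique(data$participant[is.na(data$value)])
    warning(length(bad), " participant(s) excluded (NA values): ",
            paste(bad, collapse = ", "))
    data <- data[!data$participant %in% bad, , drop = FALSE]
    excluded <- c(excluded, bad)
  }

  # split-plot decomposition by explicit sums of squares (balanced design)
  wide <- reshape(data[, c("participant", "group", "condition", "value")],
                  idvar = c("participant", "group"), timevar = "condition",
                  direction = "wide")
  y1 <- wide[[paste0("value.", conds[1])]]
  y2 <- wide[[paste0("value.", conds[2])]]
  g <- wide$group
  n_per <- table(g)
  if (any(n_per < 2)) stop("need >= 2 complete participants per group")

  subj_mean <- (y1 + y2) / 2
  grand <- mean(c(y1, y2))
  cells <- rbind(tapply(y1, g, mean), tapply(y2, g, mean)) # cond x group
  gmeans <- tapply(subj_mean, g, mean)
  cmeans <- c(mean(y1), mean(y2))

  n_total <- length(y1)
  ss_between_subj <- 2 * sum((subj_mean - grand)^2)
  ss_group <- 2 * sum(n_per * (gmeans - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_cond <- n_total * sum((cmeans - grand)^2)
  ss_cells <- sum(t(cells - grand)^2 * as.numeric(n_per))
  ss_inter <- ss_cells - ss_group - ss_cond
  ss_total <- sum((c(y1, y2) - grand)^2)
  ss_resid <- ss_total - ss_between_subj - ss_cond - ss_inter

  df_group <- 1L; df_subj <- n_total - 2L
  df_cond <- 1L; df_inter <- 1L; df_resid <- n_total - 2L
  # degenerate data (zero effect and zero error) reads as F = 0, not 0/0
  fratio <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_err <= 0) return(if (ss_eff <= 1e-24) 0 else Inf)
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  F_group <- fratio(ss_group, df_group, ss_subj_within, df_subj)
  F_cond <- fratio(ss_cond, df_cond, ss_resid, df_resid)
  F_inter <- fratio(ss_inter, df_inter, ss_resid, df_resid)

  tab <- data.frame(
    effect = c("group", "condition", "group:condition"),
    F = c(F_group, F_cond, F_inter),
    df1 = c(df_group, df_cond, df_inter),
    df2 = c(df_subj, df_resid, df_resid),
    p = c(pf(F_group, df_group, df_subj, lower.tail = FALSE),
          pf(F_cond, df_cond, df_resid, lower.tail = FALSE),
          pf(F_inter, df_inter, df_resid, lower.tail = FALSE)),
    stringsAsFactors = FALSE)

  simple <- NULL
  if (tab$p[tab$effect == "group:condition"] < alpha) {
    k <- length(groups)
    simple <- do.call(rbind, lapply(groups, function(gr) {
      d <- y2[g == gr] - y1[g == gr]
      tt <- stats::t.test(d)
      data.frame(group = gr,
                 contrast = paste(conds[2], "-", conds[1]),
                 mean_difference = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_adjusted = min(1, k * tt$p.value),
                 stringsAsFactors = FALSE)
    }))
  }
  res <- list(table = tab, simple_effects = simple, excluded = excluded,
              sums_of_squares = c(group = ss_group, subj_within = ss_subj_within,
                                  condition = ss_cond, interaction = ss_inter,
                                  residual = ss_resid, total = ss_total),
              cell_means = cells, n_per_group = as.numeric(n_per))
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> mixed 2x2 ANOVA\n")
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %-16s F(%d,%d) = %.3f, p = %.4g\n", x$table$effect[i],
                x$table$df1[i], x$table$df2[i], x$table$F[i], x$table$p[i]))
  if (!is.null(x$simple_effects)) {
    cat("  simple effects (Bonferroni):\n")
    for (i in seq_len(nrow(x$simple_effects)))
      cat(sprintf("    %s: %s = %.2f, t(%d) = %.2f, p_adj = %.4g\n",
                  x$simple_effects$group[i], x$simple_effects$contrast[i],
                  x$simple_effects$mean_difference[i],
                  x$simple_effects$df[i], x$simple_effects$t[i],
                  x$simple_effects$p_adjusted[i]))
  }
  invisible(x)
}

#' Multiple regression predicting theta contrasts
#'
#' OLS with intercept: cluster-mean regulation-associated theta contrast
#' regressed on the ERQ Reappraisal score, the ERQ Suppression score and the
#' reappraisal-minus-maintenance rating difference. Per-predictor two-sided
#' t-tests are Bonferroni-adjusted over the three predictors.
#'
#' @param theta numeric response (one value per participant)
#' @param erq_r,erq_s,rating_diff numeric predictors
#' @return object of class `regression_result`: overall F/df/p, R^2, and a
#'   coefficient table with adjusted p-values
#' @export
theta_regression <- function(theta, erq_r, erq_s, rating_diff) {
  df <- data.frame(theta = theta, erq_r = erq_r, erq_s = erq_s,
                   rating_diff = rating_diff)
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 5) stop("too few complete cases (", n, ")")
  X <- cbind(1, df$erq_r, df$erq_s, df$rating_diff)
  if (kappa(X) > 1e8)
    stop("collinear design (condition number ", signif(kappa(X), 3), ")")
  fit <- lm(theta ~ erq_r + erq_s + rating_diff, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  k <- 3L
  coef_tab <- data.frame(
    term = rownames(co),
    estimate = co[, 1], se = co[, 2], t = co[, 3],
    p = co[, 4],
    p_adjusted = c(NA, pmin(1, k * co[-1, 4])),
    row.names = NULL, stringsAsFactors = FALSE)
  fstat <- sm$fstatistic
  res <- list(F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
              p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
              r_squared = sm$r.squared, coefficients = coef_tab,
              n = n, fit = fit)
  class(res) <- "regression_result"
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> F(%d,%d) = %.3f, p = %.4g, R^2 = %.3f (n = %d)\n",
              x$df1, x$df2, x$F, x$p, x$r_squared, x$n))
  for (i in seq_len(nrow(x$coefficients)))
    cat(sprintf("  %-12s b = %9.4f  t = %7.3f  p_adj = %s\n",
                x$coefficients$term[i], x$coefficients$estimate[i],
                x$coefficients$t[i],
                ifelse(is.na(x$coefficients$p_adjusted[i]), "-",
                       format(signif(x$coefficients$p_adjusted[i], 3)))))
  invisible(x)
}
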