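# Cohort-level statistics: movement ANOVA, assessor-nested mixed models with
# ICC, group-by-dyad-type ANOVAs, and score correlations with FDR control.

#' One-way ANOVA on a cohort outcome
#'
#' Classical one-way analysis of variance of an outcome (e.g. total head
#' movement) across the three cohort groups.
#'
#' @param data Data frame with one row per dyad.
#' @param outcome,group Column names (strings) of the outcome and the
#'   grouping factor.
#' @return A one-row tibble: `F`, `df1`, `df2`, `p`, `degenerate` (`TRUE`
#'   when the within-group variance is zero so F is undefined or infinite).
#' @export
anova_oneway <- function(data, outcome, group = "group") {
  y <- data[[outcome]]
  g <- droplevels(factor(data[[group]]))
  ok <- complete.cases(y, g)
  y <- y[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stop_input("Need at least 2 non-empty groups.")
  if (any(table(g) < 2L)) stop_input("Each group needs at least 2 observations.")
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1]]
  ss_within <- tab["Residuals", "Sum Sq"]
  ss_total <- ss_within + tab[1, "Sum Sq"]
  scale_ref <- max(sum(y^2), .Machine$double.xmin)
  degenerate <- !is.finite(tab[1, "F value"]) ||
    ss_total <= 1e-12 * scale_ref ||       # constant outcome
    ss_within <= 1e-12 * max(ss_total, .Machine$double.xmin)  # zero within-group noise
  tibble(
    F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab["Residuals", "Df"],
    p = tab[1, "Pr(>F)"], degenerate = degenerate
  )
}

#' Assessor-nested linear mixed model for strength or delay of synchrony
#'
#' Fits the cohort model for a synchrony outcome: fixed effects of group
#' (reference level HC), participant sex, assessor sex and their
#' interaction, with a random intercept per assessor to absorb the nesting
#' of dyads within assessors. Restricted maximum likelihood is used, with
#' Satterthwaite degrees of freedom for fixed-effect p values and Wald 95%
#' confidence intervals. The intraclass correlation
#' `ICC = var(assessor) / (var(assessor) + var(residual))` quantifies how
#' much of the outcome variance is attributable to the assessor. A singular
#' (boundary) fit is flagged and reported with ICC at the 0 boundary.
#'
#' @param data Cohort table with columns `group`, `participant_sex`,
#'   `assessor_sex`, `assessor_id` and the outcome.
#' @param outcome `"strength"` or `"delay_s"` (any numeric column name is
#'   accepted).
#' @return An object of class `synchrony_mixed_model`: list with the
#'   `lmerMod` fit, `fixed` (tibble: term, estimate, conf.low, conf.high,
#'   df, statistic, p.value), `var_assessor`, `var_residual`, `icc`,
#'   `singular`, `outcome`. Use [tidy()] / [glance()] for tabular views.
#' @export
fit_strength_model <- function(data, outcome = "strength") {
  needed <- c(outcome, "group", "participant_sex", "assessor_sex", "assessor_id")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop_input(sprintf("Missing column(s): %s.",
                       paste(missing_cols, collapse = ", ")))
  }
  df <- data.frame(
    y = data[[outcome]],
    group = stats::relevel(factor(data$group, levels = c("HC", "SUB", "CHR")),
                           ref = "HC"),
    participant_sex = factor(data$participant_sex),
    assessor_sex = factor(data$assessor_sex),
    assessor_id = factor(data$assessor_id)
  )
  df <- df[complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$assessor_id)) < 2L) {
    stop_input("Need at least 2 assessors to fit a random intercept.")
  }
  has_sex_contrast <- nlevels(droplevels(df$participant_sex)) > 1L &&
    nlevels(droplevels(df$assessor_sex)) > 1L
  form <- if (has_sex_contrast) {
    y ~ group + participant_sex * assessor_sex + (1 | assessor_id)
  } else {
    y ~ group + (1 | assessor_id)
  }
  fit <- lmerTest::lmer(form, data = df, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_assessor <- vc$vcov[vc$grp == "assessor_id"]
  var_residual <- vc$vcov[vc$grp == "Residual"]
  icc <- var_assessor / (var_assessor + var_residual)
  coefs <- as.data.frame(stats::coef(summary(fit)))
  ci <- stats::confint(fit, parm = "beta_", method = "Wald")
  fixed <- tibble(
    term = rownames(coefs),
    estimate = coefs$Estimate,
    std.error = coefs$`Std. Error`,
    conf.low = ci[, 1], conf.high = ci[, 2],
    df = coefs$df, statistic = coefs$`t value`,
    p.value = coefs$`Pr(>|t|)`
  )
  structure(
    list(fit = fit, fixed = fixed, var_assessor = var_assessor,
         var_residual = var_residual, icc = icc, singular = singular,
         outcome = outcome, n = nrow(df),
         n_assessors = nlevels(droplevels(df$assessor_id))),
    class = "synchrony_mixed_model"
  )
}

#' @export
print.synchrony_mixed_model <- function(x, ...) {
  cat(sprintf(
    "<synchrony_mixed_model> outcome %s: %d dyads in %d assessors, ICC = %.3f%s\n",
    x$outcome, x$n, x$n_assessors, x$icc,
    if (x$singular) " (singular fit, boundary)" else ""
  ))
  print(x$fixed)
  invisible(x)
}

#' Post hoc pairwise group contrasts from a fitted synchrony model
#'
#' Estimated marginal means of the three groups from the mixed model, with
#' all pairwise contrasts and Benjamini-Hochberg adjusted p values.
#'
#' @param model A `synchrony_mixed_model` from [fit_strength_model()].
#' @return A tibble: `contrast`, `estimate`, `std.error`, `df`,
#'   `statistic`, `p.value`, `p.adjusted`.
#' @export
posthoc_group_contrasts <- function(model) {
  if (!inherits(model, "synchrony_mixed_model")) {
    stop_input("`model` must come from fit_strength_model().")
  }
  emm <- emmeans::emmeans(model$fit, "group")
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  tibble(
    contrast = as.character(ctr$contrast),
    estimate = ctr$estimate, std.error = ctr$SE, df = ctr$df,
    statistic = ctr$t.ratio, p.value = ctr$p.value,
    p.adjusted = bh_adjust(ctr$p.value)
  )
}

#' Two-way group-by-dyad-type ANOVA
#'
#' 3 (group) x 4 (dyad type: assessor sex crossed with participant sex)
#' analysis of variance with Type-II sums of squares (robust to the
#' unbalanced cells a recruited cohort produces) and generalized eta-squared
#' effect sizes `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param data Cohort table.
#' @param outcome Outcome column name.
#' @param group,dyad_type Factor column names.
#' @return A tibble with one row per term (`group`, `dyad_type`,
#'   `group:dyad_type`): `sumsq`, `df`, `statistic`, `p.value`, `ges`.
#'   Empty design cells are reported via a message; terms remain estimable
#'   under Type-II sums of squares where the data allow.
#' @export
anova_twoway <- function(data, outcome, group = "group",
                         dyad_type = "dyad_type") {
  df <- data.frame(
    y = data[[outcome]],
    g = droplevels(factor(data[[group]])),
    d = droplevels(factor(data[[dyad_type]]))
  )
  df <- df[complete.cases(df), , drop = FALSE]
  if (nlevels(df$g) < 2L || nlevels(df$d) < 2L) {
    stop_input("Both factors need at least 2 observed levels.")
  }
  cells <- table(df$g, df$d)
  if (any(cells == 0L)) {
    inform(sprintf("%d empty group x dyad-type cell(s); Type-II SS computed on the estimable terms.",
                   sum(cells == 0L)))
  }
  fit <- lm(y ~ g * d, data = df)
  tab <- car::Anova(fit, type = 2, singular.ok = TRUE)
  ss_resid <- tab["Residuals", "Sum Sq"]
  terms_map <- c(g = group, d = dyad_type,
                 `g:d` = paste0(group, ":", dyad_type))
  rows <- rownames(tab)
  keep <- rows != "Residuals"
  tibble(
    term = unname(terms_map[rows[keep]]),
    sumsq = tab[keep, "Sum Sq"],
    df = tab[keep, "Df"],
    statistic = tab[keep, "F value"],
    p.value = tab[keep, "Pr(>F)"],
    ges = tab[keep, "Sum Sq"] / (tab[keep, "Sum Sq"] + ss_resid)
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a family of p values: sorted ascending, each
#' p(i) is scaled by n/i, cumulative minima are taken from the largest rank
#' down (enforcing monotonicity), and results are capped at 1.
#'
#' @param pvals Numeric vector of p values in `[0, 1]` (`NA` allowed and
#'   passed through).
#' @return Adjusted p values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop_input("`pvals` must be numeric.")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop_input("All p values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Pearson correlations of a synchrony outcome with score columns, with FDR
#'
#' Correlates one synchrony outcome with each score column (symptom or
#' functioning scales) over an optional group subset, using pairwise-complete
#' observations, and adjusts the family of p values by Benjamini-Hochberg.
#' Score columns that are constant (correlation undefined) or have fewer
#' than 4 complete pairs are flagged and excluded from the adjusted family.
#'
#' @param data Cohort table.
#' @param outcome Outcome column name (`"strength"` or `"delay_s"`).
#' @param score_columns Character vector of score column names forming one
#'   FDR family.
#' @param groups Optional character vector restricting to these `group`
#'   levels (e.g. `"CHR"` or `c("CHR", "SUB")`); `NULL` uses all rows.
#' @return A tibble: `score`, `n`, `r`, `p`, `p_adjusted`, `flag`
#'   (`"ok"`, `"constant"`, or `"too_few"`).
#' @export
pearson_with_fdr <- function(data, outcome, score_columns, groups = NULL) {
  if (!is.null(groups)) data <- data[data$group %in% groups, , drop = FALSE]
  y <- data[[outcome]]
  rows <- purrr::map(score_columns, function(sc) {
    x <- data[[sc]]
    if (is.null(x)) stop_input(sprintf("No column `%s` in `data`.", sc))
    ok <- complete.cases(x, y)
    n <- sum(ok)
    if (n < 4L) {
      return(tibble(score = sc, n = n, r = NA_real_, p = NA_real_,
                    flag = "too_few"))
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(score = sc, n = n, r = NA_real_, p = NA_real_,
                    flag = "constant"))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble(score = sc, n = n, r = unname(ct$estimate), p = ct$p.value,
           flag = "ok")
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- NA_real_
  usable <- out$flag == "ok"
  out$p_adjusted[usable] <- bh_adjust(out$p[usable])
  dplyr::relocate(out, "flag", .after = "p_adjusted")
}
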