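#' One-way or additive two-way ANOVA over experimental conditions
#'
#' Condition comparison for image-quality metrics (percent relative
#' intensity, or SNR at a fixed imaging depth): a main-effects-only linear
#' model — one factor, or two factors without an interaction term — with
#' an F test per factor. Each row of `data` is one sample (inter-sample
#' variance: the spread of a metric across samples of a condition, not the
#' within-slice spread of region pairs). For unbalanced designs type-II
#' sums of squares are used and declared in the result; on balanced
#' designs the SS types coincide.
#'
#' Normality and homoscedasticity are not tested — the typical group sizes
#' in these experiments (2–4 samples) cannot support such tests — and the
#' result carries a caveat line saying so.
#'
#' @param data Data.frame with one row per sample.
#' @param metric Name of the numeric response column.
#' @param factors Character vector of one or two factor column names.
#' @return A data.frame of class `anova_conditions` with columns `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p_value` (one row per factor
#'   plus a residual row), and attributes `ss_type` and `caveat`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' anova_conditions(d, "y", "g")  # F = 13.5 on (1, 4) df
#' @export
anova_conditions <- function(data, metric, factors) {
  stopifnot(is.data.frame(data), metric %in% names(data),
            length(factors) %in% 1:2, all(factors %in% names(data)))
  if (!is.numeric(data[[metric]])) stop("metric column must be numeric")
  d <- data.frame(.y = data[[metric]])
  for (f in factors) {
    lev <- factor(data[[f]])
    if (nlevels(droplevels(lev)) < 2L) {
      stop(sprintf("factor '%s' needs >= 2 observed levels", f))
    }
    d[[f]] <- droplevels(lev)
  }
  if (nrow(d) < sum(vapply(factors, function(f) nlevels(d[[f]]) - 1L,
                           integer(1))) + 2L) {
    stop("too few observations for the requested design")
  }
  form <- stats::as.formula(paste(".y ~", paste(factors, collapse = " + ")))
  fit <- lm(form, data = d)
  if (fit$rank < length(coef(fit))) {
    stop(sprintf("singular design: factors %s are confounded",
                 paste(factors, collapse = ", ")))
  }
  tab <- if (length(factors) == 1L) {
    a <- stats::anova(fit)
    data.frame(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
               statistic = a$`F value`, p_value = a$`Pr(>F)`)
  } else {
    a <- car::Anova(fit, type = 2)
    data.frame(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
               statistic = a$`F value`, p_value = a$`Pr(>F)`)
  }
  tab$meansq <- tab$sumsq / tab$df
  tab <- tab[, c("term", "df", "sumsq", "meansq", "statistic", "p_value")]
  attr(tab, "ss_type") <- if (length(factors) == 1L) "I (one-way)" else "II"
  attr(tab, "caveat") <-
    "normality and homoscedasticity not tested (group sizes too small)"
  class(tab) <- c("anova_conditions", "data.frame")
  tab
}

#' Tukey HSD pairwise comparisons for one factor
#'
#' Studentized-range-based pairwise follow-up to a one-way ANOVA: for
#' every pair of factor levels, the mean difference, the Tukey-adjusted p
#' value, and a significance flag at `alpha`. With exactly two levels the
#' adjusted p equals the pooled two-sample t-test p.
#'
#' @param data Data.frame with one row per sample.
#' @param metric Name of the numeric response column.
#' @param factor_name Name of the grouping column.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of class `tukey_conditions` with columns
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd_conditions <- function(data, metric, factor_name, alpha = 0.05) {
  stopifnot(is.data.frame(data), metric %in% names(data),
            factor_name %in% names(data), alpha > 0, alpha < 1)
  d <- data.frame(.y = data[[metric]], .g = droplevels(factor(data[[factor_name]])))
  if (nlevels(d$.g) < 2L) stop("need >= 2 factor levels")
  if (any(table(d$.g) < 1L)) stop("every level needs >= 1 observation")
  fit <- aov(.y ~ .g, data = d)
  sigma2 <- sum(fit$residuals^2) / fit$df.residual
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$.g
  out <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL)
  if (is.finite(sigma2) && sigma2 == 0) {
    # degenerate: zero residual variance; identical groups are certainly
    # equal (p = 1), distinct groups certainly differ (p -> 0)
    out$p_adj <- ifelse(abs(out$diff) < 1e-12, 1, 0)
  }
  out$significant <- out$p_adj < alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("tukey_conditions", "data.frame")
  out
}
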