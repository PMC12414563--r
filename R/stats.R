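#' Planned two-sample contrast with Bonferroni correction
#'
#' Classical two-tailed Student's t-test (pooled variance by default,
#' Welch optionally) on per-subject scalars, with the p-value multiplied by
#' the family size and capped at 1. Subjects with missing values (for
#' example an undefined directional index) are dropped and counted.
#'
#' @param values_low,values_high per-subject scalars.
#' @param family_size Bonferroni family size (default 1 = no correction).
#' @param welch use Welch's unequal-variance t.
#' @return object of class `contrast_result`: `t`, `df`, `p_raw`,
#'   `p_bonferroni`, `mean_low`, `mean_high`, `sem_low`, `sem_high`,
#'   `n_low`, `n_high`, `n_dropped`, `degenerate`.
#' @export
planned_contrast <- function(values_low, values_high, family_size = 1L,
                             welch = FALSE) {
  n_dropped <- sum(is.na(values_low)) + sum(is.na(values_high))
  x <- values_low[!is.na(values_low)]
  y <- values_high[!is.na(values_high)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 non-missing values per group")
  }
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  degenerate <- FALSE
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 <= 0) {
    degenerate <- TRUE
    t <- NA_real_
    p <- 1
  } else {
    t <- (m1 - m2) / sqrt(se2)
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p_raw = p,
                 p_bonferroni = min(1, p * family_size),
                 mean_low = m1, mean_high = m2,
                 sem_low = stats::sd(x) / sqrt(n1),
                 sem_high = stats::sd(y) / sqrt(n2),
                 n_low = n1, n_high = n2, n_dropped = n_dropped,
                 family_size = family_size, degenerate = degenerate),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("t(%.1f) = %.3f, p = %.4g (Bonferroni x%d: %.4g)\n",
              x$df, x$t, x$p_raw, x$family_size, x$p_bonferroni))
  cat(sprintf("  low:  mean %.4g (SEM %.3g, n %d)\n",
              x$mean_low, x$sem_low, x$n_low))
  cat(sprintf("  high: mean %.4g (SEM %.3g, n %d)\n",
              x$mean_high, x$sem_high, x$n_high))
  invisible(x)
}

#' Omnibus linear mixed model with subject random intercept
#'
#' Fits `value ~ group * band` (plus `* direction` when a `direction`
#' column is present) with a per-subject random intercept via
#' \pkg{lme4}, and reports a chi-square per fixed term (Wald type-II
#' tests from \pkg{car}). This step delegates entirely to standard
#' mixed-model machinery; only the orchestration is local. A singular fit
#' triggers a warning and sets `fallback = TRUE`, signalling that per-band
#' planned contrasts should be interpreted instead.
#'
#' @param data tidy data frame with columns `subject`, `group`, `band`,
#'   optionally `direction`, and `value`. Missing values are dropped.
#' @return object of class `omnibus_result`: `table` (data frame: term,
#'   chisq, df, p), `model` (the lmerMod fit), `fallback`.
#' @export
omnibus_model <- function(data) {
  stopifnot(all(c("subject", "group", "band", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  data$group <- factor(data$group)
  data$band <- factor(data$band)
  has_dir <- "direction" %in% names(data)
  form <- if (has_dir) {
    data$direction <- factor(data$direction)
    value ~ group * band * direction + (1 | subject)
  } else {
    value ~ group * band + (1 | subject)
  }
  fit <- lme4::lmer(form, data = data, REML = FALSE)
  fallback <- lme4::isSingular(fit)
  if (fallback) {
    warning("singular mixed-model fit; interpret per-band contrasts instead")
  }
  an <- car::Anova(fit, type = "II")
  tab <- data.frame(term = rownames(an),
                    chisq = an[["Chisq"]],
                    df = an[["Df"]],
                    p = an[["Pr(>Chisq)"]],
                    row.names = NULL)
  structure(list(table = tab, model = fit, fallback = fallback),
            class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  cat("omnibus mixed model (chi-square per term):\n")
  print(x$table, row.names = FALSE)
  if (x$fallback) cat("  [singular fit: rely on planned contrasts]\n")
  invisible(x)
}
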