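#' Tukey ladder-of-powers transformation
#'
#' Selects the power lambda from the ladder that best normalizes the
#' data, scored by the probability-plot correlation (correlation of the
#' sorted sample with standard normal quantiles). Nonpositive data are
#' shifted by `1e-6 + |min|` first. The transform is strictly monotone
#' increasing on the input range for every lambda: `x^lambda` for
#' lambda > 0, `log(x)` for lambda = 0, `-(x^lambda)` for lambda < 0.
#'
#' @param x Numeric vector with at least 3 finite, non-constant values.
#' @param lambdas Ladder to search; default `{-2, -1, -0.5, 0, 0.5, 1, 2}`.
#' @return Object of class `TukeyTransform`: list with `lambda`, `shift`,
#'   `values` (transformed data), `score` (normality score of the chosen
#'   lambda), `scores` (all scores).
#' @export
tukey_transform <- function(x, lambdas = c(-2, -1, -0.5, 0, 0.5, 1, 2)) {
  x <- as.numeric(x)
  ok <- is.finite(x)
  if (sum(ok) < 3L) stop("need at least 3 finite values", call. = FALSE)
  if (length(unique(x[ok])) == 1L) stop("constant input", call. = FALSE)
  shift <- if (min(x[ok]) <= 0) 1e-6 + abs(min(x[ok])) else 0
  xs <- x + shift
  apply_lambda <- function(v, lam) {
    if (lam > 0) v^lam else if (lam == 0) log(v) else -(v^lam)
  }
  qn <- stats::qnorm(stats::ppoints(sum(ok)))
  scores <- vapply(lambdas, function(lam) {
    y <- apply_lambda(xs[ok], lam)
    if (!all(is.finite(y)) || stats::sd(y) == 0) return(-Inf)
    stats::cor(sort(y), qn)
  }, numeric(1))
  best <- which.max(scores)
  structure(list(lambda = lambdas[best], shift = shift,
                 values = apply_lambda(xs, lambdas[best]),
                 score = scores[best],
                 scores = stats::setNames(scores, lambdas)),
            class = "TukeyTransform")
}

#' @export
print.TukeyTransform <- function(x, ...) {
  cat(sprintf("Tukey ladder transform: lambda = %g, shift = %g, score = %.4f\n",
              x$lambda, x$shift, x$score))
  invisible(x)
}

#' Random-intercept group-comparison model
#'
#' Fits the group-comparison model used for nested histology or culture
#' data: the (Tukey-transformed) outcome against the fixed-effect terms,
#' with a random intercept for the case / culture-replicate grouping so
#' repeated measurements of a case do not pseudoreplicate. Fitted by
#' REML; per-term F tests use the Satterthwaite denominator-df
#' approximation (approximate by construction). With zero between-case
#' variance and a balanced design the F statistic approaches the one-way
#' fixed-effects ANOVA value.
#'
#' @param data Tidy data frame, one row per observation (stack or well).
#' @param outcome Outcome column name.
#' @param fixed_terms Character vector of fixed-effect column names
#'   (e.g. cohort, region, APOE4 status, sex, age).
#' @param random_group Grouping column for the random intercept (case or
#'   replicate id).
#' @param transform Apply [tukey_transform()] to the outcome first
#'   (default `TRUE`); the transformation record is kept in the result.
#' @return Object of class `GroupModelFit`: `fit` (the `lmerModLmerTest`
#'   object), `anova` (per-term F table with numerator/denominator df
#'   and p), `transform` (or `NULL`), `singular` and `converged` flags,
#'   plus the call ingredients.
#' @export
fit_group_model <- function(data, outcome, fixed_terms, random_group,
                            transform = TRUE) {
  data <- as.data.frame(data)
  for (v in c(outcome, fixed_terms, random_group))
    if (!v %in% names(data))
      stop("column '", v, "' not in data", call. = FALSE)
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (!nzchar(data[[random_group]][1]) || anyNA(data[[random_group]]))
    stop("case ids must be non-empty", call. = FALSE)
  factors <- fixed_terms[!vapply(data[fixed_terms], is.numeric, logical(1))]
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L)
      stop("fixed term '", f, "' has fewer than 2 levels", call. = FALSE)
  }
  tr <- NULL
  yname <- outcome
  if (transform) {
    tr <- tukey_transform(data[[outcome]])
    data$.y <- tr$values
    yname <- ".y"
  }
  fml <- stats::as.formula(paste(
    yname, "~", paste(fixed_terms, collapse = " + "),
    "+ (1 |", random_group, ")"))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  conv <- fit@optinfo$conv$lme4
  an <- as.data.frame(stats::anova(fit))
  an$term <- rownames(an)
  rownames(an) <- NULL
  structure(list(fit = fit, anova = an, transform = tr,
                 singular = lme4::isSingular(fit),
                 converged = is.null(conv$messages) ||
                   length(conv$messages) == 0L,
                 outcome = outcome, fixed_terms = fixed_terms,
                 random_group = random_group, data = data),
            class = "GroupModelFit")
}

#' @export
print.GroupModelFit <- function(x, ...) {
  cat("Random-intercept group model:",
      deparse(stats::formula(x$fit)), "\n")
  if (!is.null(x$transform))
    cat(sprintf("  outcome Tukey-transformed (lambda = %g, shift = %g)\n",
                x$transform$lambda, x$transform$shift))
  if (x$singular) cat("  note: singular fit (between-case variance ~ 0)\n")
  if (!x$converged) cat("  WARNING: convergence messages reported\n")
  print(x$anova, digits = 4)
  invisible(x)
}

#' Tukey-corrected pairwise contrasts
#'
#' All pairwise contrasts between the levels of one fixed factor of a
#' [fit_group_model()] fit, with Tukey family-wise adjustment of the
#' p values. For a 2-level factor the family has a single contrast and
#' the adjusted p equals the unadjusted p.
#'
#' @param fit A `GroupModelFit`.
#' @param factor_name Name of a factor among the fit's fixed terms.
#' @return Data frame: `contrast`, `estimate`, `SE`, `df`, `t_ratio`,
#'   `p_adjusted`.
#' @export
pairwise_contrasts <- function(fit, factor_name) {
  stopifnot(inherits(fit, "GroupModelFit"))
  if (!factor_name %in% fit$fixed_terms)
    stop("unknown factor '", factor_name, "'", call. = FALSE)
  if (is.numeric(fit$data[[factor_name]]))
    stop("'", factor_name, "' is numeric, not a factor", call. = FALSE)
  if (nlevels(factor(fit$data[[factor_name]])) < 2L)
    stop("factor must have >= 2 levels", call. = FALSE)
  em <- emmeans::emmeans(fit$fit, specs = factor_name,
                         lmer.df = "satterthwaite")
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  data.frame(contrast = pr$contrast, estimate = pr$estimate, SE = pr$SE,
             df = pr$df, t_ratio = pr$t.ratio, p_adjusted = pr$p.value)
}

#' Fold change between two groups of cases
#'
#' Ratio of group means of the case-level mean outcome (so duplicated
#' within-case observations cannot inflate the estimate), with a
#' seeded case-level bootstrap percentile confidence interval. Case
#' medians are available via `stat = "median"`.
#'
#' @param data Observation-level table.
#' @param outcome,case_col,group_col Column names.
#' @param group_a,group_b Numerator and denominator group labels.
#' @param stat Case-level summary, `"mean"` (default) or `"median"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @param conf_level Confidence level.
#' @return List: `ratio`, `ci` (length 2), `n_cases` (per group).
#' @export
fold_change <- function(data, outcome, case_col, group_col,
                        group_a, group_b, stat = c("mean", "median"),
                        n_boot = 1000L, seed = 1L, conf_level = 0.95) {
  stat <- match.arg(stat)
  f <- match.fun(stat)
  data <- as.data.frame(data)
  case_stat <- function(g) {
    d <- data[data[[group_col]] == g, ]
    if (nrow(d) == 0L) stop("group '", g, "' is empty", call. = FALSE)
    as.numeric(tapply(d[[outcome]], d[[case_col]], f))
  }
  a <- case_stat(group_a)
  b <- case_stat(group_b)
  if (mean(b) <= 0)
    stop("denominator group mean must be > 0", call. = FALSE)
  ratio <- mean(a) / mean(b)
  ci <- withr::with_seed(as.integer(seed), {
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(sample(a, replace = TRUE)) / mean(sample(b, replace = TRUE))
    }, numeric(1))
    stats::quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                    names = FALSE)
  })
  list(ratio = ratio, ci = ci,
       n_cases = c(length(a), length(b)))
}

#' Correlation between two quantities
#'
#' Rank (Spearman, default) or linear (Pearson) correlation with its
#' p value.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, non-constant.
#' @param method `"rank"` or `"linear"`.
#' @return List `coefficient`, `p_value`, `method`.
#' @export
correlate <- function(x, y, method = c("rank", "linear")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = if (method == "rank") "spearman" else "pearson"))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       method = method)
}
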