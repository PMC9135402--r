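#' Odds-ratio comparison of a summary statistic between two network ensembles
#'
#' Fits a logistic regression of ensemble membership (reference ensemble
#' coded 0, the other 1) on the chosen summary statistic; the exponentiated
#' slope is the odds ratio: OR > 1 means the non-reference ensemble has
#' larger values of the statistic. The 95% CI is Wald on the log-odds scale
#' (profile-likelihood optional) and significance comes from a likelihood
#' ratio test against the intercept-only model. Rows with an undefined
#' statistic are excluded (counts recorded). Complete or quasi-separation is
#' detected and flagged rather than reported as a spurious CI.
#'
#' @param ensemble_a,ensemble_b data frames of per-replicate summaries (e.g.
#'   [run_accessibility_ensemble()] output).
#' @param statistic column name of the summary statistic to compare.
#' @param reference which ensemble is the control coded 0: `"A"` (default)
#'   or `"B"`.
#' @param ci_method `"wald"` (default) or `"profile"`.
#' @return An object of class `or_comparison`: `statistic_name`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `lrt_p`, `n_a`, `n_b`, `n_dropped_a`, `n_dropped_b`,
#'   `separation_flag`.
#' @export
odds_ratio_compare <- function(ensemble_a, ensemble_b, statistic,
                               reference = c("A", "B"),
                               ci_method = c("wald", "profile")) {
  reference <- match.arg(reference)
  ci_method <- match.arg(ci_method)
  xa <- ensemble_a[[statistic]]
  xb <- ensemble_b[[statistic]]
  if (is.null(xa) || is.null(xb))
    stop("statistic '", statistic, "' not found in both ensembles", call. = FALSE)
  n_dropped_a <- sum(is.na(xa)); n_dropped_b <- sum(is.na(xb))
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (length(xa) == 0 || length(xb) == 0)
    stop("an ensemble has no defined values for '", statistic, "'", call. = FALSE)
  x <- c(xa, xb)
  y <- c(rep(0L, length(xa)), rep(1L, length(xb)))
  if (reference == "B") y <- 1L - y
  if (stats::var(x) == 0)
    stop("statistic is constant across both ensembles; model degenerate", call. = FALSE)

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  separation <- !fit$converged ||
    (sep_warn && (abs(beta) > 15 || se > 100))

  if (ci_method == "profile" && !separation) {
    ci <- suppressMessages(stats::confint(fit, "x", level = 0.95))
  } else {
    ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  }
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  lrt_stat <- null_fit$deviance - fit$deviance
  lrt_p <- stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)

  structure(list(
    statistic_name = statistic,
    odds_ratio = exp(beta),
    ci_low = if (separation) NA_real_ else exp(ci[1]),
    ci_high = if (separation) NA_real_ else exp(ci[2]),
    log_or = beta, se_log_or = se,
    lrt_stat = lrt_stat, lrt_p = lrt_p,
    n_a = length(xa), n_b = length(xb),
    n_dropped_a = n_dropped_a, n_dropped_b = n_dropped_b,
    separation_flag = separation,
    reference = reference
  ), class = "or_comparison")
}

#' @export
print.or_comparison <- function(x, ...) {
  cat(sprintf("OR comparison on '%s' (reference = ensemble %s)\n",
              x$statistic_name, x$reference))
  cat(sprintf("  OR = %.4g  95%% CI [%.4g, %.4g]  LRT p = %.3g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$lrt_p))
  if (x$separation_flag)
    cat("  WARNING: complete/quasi-separation detected; CI not reported\n")
  cat(sprintf("  n = %d vs %d (dropped %d / %d undefined)\n",
              x$n_a, x$n_b, x$n_dropped_a, x$n_dropped_b))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; never smaller than the input, invariant to
#' input order, capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
fdr_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Poisson regression of distance-to-peak on landscape ruggedness
#'
#' Fits `glm(min_dist_to_peak ~ n_peaks, family = poisson)` over replicate
#' summaries with a defined distance to peak: a negative slope means more
#' rugged landscapes (more peaks) have shorter accessible distances to the
#' nearest peak.
#'
#' @param summaries data frame with columns `min_dist_to_peak` and `n_peaks`
#'   (e.g. pooled [run_accessibility_ensemble()] output).
#' @return List of class `ruggedness_regression`: `beta`, `ci_low`, `ci_high`
#'   (95% Wald), `p` (likelihood ratio test), `n`.
#' @export
ruggedness_regression <- function(summaries) {
  d <- summaries[!is.na(summaries$min_dist_to_peak) & !is.na(summaries$n_peaks), ]
  if (nrow(d) < 2 || length(unique(d$n_peaks)) < 2)
    stop("need >= 2 distinct peak counts with defined distances", call. = FALSE)
  fit <- stats::glm(min_dist_to_peak ~ n_peaks, family = stats::poisson(), data = d)
  beta <- stats::coef(fit)[["n_peaks"]]
  se <- sqrt(stats::vcov(fit)["n_peaks", "n_peaks"])
  null_fit <- stats::glm(min_dist_to_peak ~ 1, family = stats::poisson(), data = d)
  p <- stats::pchisq(null_fit$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  structure(list(
    beta = beta,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    p = p, n = nrow(d), model = "glm(min_dist_to_peak ~ n_peaks, poisson)"
  ), class = "ruggedness_regression")
}

#' @export
print.ruggedness_regression <- function(x, ...) {
  cat(x$model, "\n")
  cat(sprintf("  beta = %.4g  95%% CI [%.4g, %.4g]  LRT p = %.3g  (n = %d)\n",
              x$beta, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Omnibus and pairwise comparison of a statistic across >= 3 ensembles
#'
#' Runs a one-way ANOVA and a Kruskal-Wallis omnibus test on the statistic
#' across labelled ensembles, followed by Dunn-type pairwise rank comparisons
#' (normal approximation with tie correction) adjusted by Benjamini-Hochberg.
#'
#' @param ensembles named list of >= 3 summary data frames.
#' @param statistic column name to compare.
#' @return List of class `multigroup_comparison`: `anova_p`, `kruskal_p`,
#'   `medians`, and `pairwise` (data frame with z, p, fdr_p per pair).
#' @export
multigroup_compare <- function(ensembles, statistic) {
  if (length(ensembles) < 3) stop("need >= 3 groups", call. = FALSE)
  if (is.null(names(ensembles)) || any(names(ensembles) == ""))
    stop("ensembles must be named", call. = FALSE)
  vals <- lapply(ensembles, function(e) {
    v <- e[[statistic]]
    v[!is.na(v)]
  })
  if (any(vapply(vals, length, integer(1)) == 0))
    stop("empty group after removing undefined values", call. = FALSE)
  if (any(vapply(vals, length, integer(1)) < 2))
    stop("each group needs >= 2 values", call. = FALSE)
  x <- unlist(vals, use.names = FALSE)
  g <- factor(rep(names(vals), vapply(vals, length, integer(1))),
              levels = names(vals))
  anova_p <- summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1]
  kw <- stats::kruskal.test(x, g)
  medians <- vapply(vals, stats::median, numeric(1))
  structure(list(
    statistic_name = statistic,
    anova_p = anova_p, kruskal_p = kw$p.value,
    medians = medians,
    pairwise = dunn_pairwise(x, g)
  ), class = "multigroup_comparison")
}

# Dunn-type pairwise rank z-tests with tie correction; BH-adjusted.
dunn_pairwise <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  lv <- levels(g)
  combs <- utils::combn(lv, 2)
  z <- numeric(ncol(combs))
  for (c_i in seq_len(ncol(combs))) {
    a <- combs[1, c_i]; b <- combs[2, c_i]
    sigma <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[c_i] <- (mean_rank[[a]] - mean_rank[[b]]) / sigma
  }
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(
    group_a = combs[1, ], group_b = combs[2, ],
    z = z, p = p, fdr_p = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.multigroup_comparison <- function(x, ...) {
  cat(sprintf("Multigroup comparison on '%s'\n", x$statistic_name))
  cat(sprintf("  ANOVA p = %.3g; Kruskal-Wallis p = %.3g\n", x$anova_p, x$kruskal_p))
  cat("  medians:", paste(sprintf("%s=%.4g", names(x$medians), x$medians),
                          collapse = ", "), "\n")
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Pairwise Tukey HSD across labelled classes
#'
#' One-way layout Tukey honest-significant-difference comparisons, with an
#' additional Benjamini-Hochberg adjusted column as reported alongside the
#' interspecies distance comparisons.
#'
#' @param values numeric response.
#' @param class class labels (>= 2 classes, >= 2 values each).
#' @return Data frame with one row per class pair: `diff`, `lwr`, `upr`, `p`,
#'   `fdr_p`.
#' @export
tukey_hsd <- function(values, class) {
  keep <- !is.na(values) & !is.na(class)
  values <- values[keep]
  class <- factor(as.character(class[keep]))
  if (nlevels(class) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(table(class) < 2)) stop("each class needs >= 2 values", call. = FALSE)
  fit <- stats::aov(values ~ class)
  tk <- stats::TukeyHSD(fit)$class
  out <- data.frame(
    pair = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p = tk[, "p adj"],
    stringsAsFactors = FALSE
  )
  out$fdr_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
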