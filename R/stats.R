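#' Statistical test result container
#'
#' Uniform record for every test in the battery: the effect name, the kind of
#' statistic (t or F), its value, degrees of freedom, raw and adjusted
#' p-values, and the adjustment applied. For t statistics the sign convention
#' is recorded in `direction` (for hemisphere tests, positive = rightward).
#'
#' @param effect character label.
#' @param kind `"t"` or `"F"`.
#' @param statistic statistic value.
#' @param df degrees of freedom (length 1 for t, length 2 for F).
#' @param p_raw raw p-value.
#' @param p_adjusted adjusted p-value (defaults to `p_raw`).
#' @param adjustment `"none"`, `"bonferroni"`, or `"fdr_bh"`.
#' @param direction free-text sign convention.
#' @export
stat_result <- function(effect, kind, statistic, df, p_raw,
                        p_adjusted = p_raw,
                        adjustment = c("none", "bonferroni", "fdr_bh"),
                        direction = NA_character_) {
  adjustment <- match.arg(adjustment)
  stopifnot(p_raw >= 0, p_raw <= 1, p_adjusted >= p_raw - 1e-15)
  structure(list(effect = effect, kind = match.arg(kind, c("t", "F")),
                 statistic = statistic, df = df, p_raw = p_raw,
                 p_adjusted = p_adjusted, adjustment = adjustment,
                 direction = direction),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g (adjusted %.4g, %s)\n",
              x$effect, x$kind, x$statistic,
              paste(round(x$df, 2), collapse = ", "),
              x$p_raw, x$p_adjusted, x$adjustment))
  invisible(x)
}

# validate a covariate data.frame: numeric, no NAs unless allowed, not
# constant; returns the (unchanged) frame
check_covariates <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (!is.numeric(v)) stop(sprintf("covariate '%s' must be numeric", nm))
    if (stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v)))
      stop(sprintf("covariate '%s' is constant", nm))
  }
  covariates
}

# stop naming the aliased column if a fitted lm is rank deficient
check_full_rank <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("collinear model term(s): ",
         paste(names(co)[is.na(co)], collapse = ", "))
  invisible(fit)
}

#' Within-group hemisphere asymmetry test
#'
#' Tests whether a network measure differs between hemispheres within one
#' group, adjusting for covariates. The two-level repeated-measures GLM with
#' hemisphere as the within-subject factor is realized as its exactly
#' equivalent paired-difference regression: the per-subject difference
#' `d = right - left` is regressed on the mean-centered covariates and the
#' intercept is tested. Positive t = rightward asymmetry.
#'
#' @param left,right paired per-subject measure values.
#' @param covariates data.frame of per-subject numeric covariates
#'   (e.g. age, sex code, hemispheric-ICV difference, TR, TE).
#' @return a [stat_result()] (t statistic).
#' @export
hemisphere_repeated_test <- function(left, right, covariates) {
  stopifnot(length(left) == length(right))
  if (anyNA(left) || anyNA(right)) stop("left/right values must be complete")
  covariates <- check_covariates(covariates)
  n <- length(left)
  if (n < ncol(covariates) + 2)
    stop("need at least (number of covariates + 2) subjects")
  d <- right - left
  if (all(d == d[1])) {
    # degenerate paired data: a constant difference has zero residual
    # variance, so the test is decided exactly
    return(stat_result("hemisphere (right - left)", "t",
                       statistic = if (d[1] == 0) 0 else sign(d[1]) * Inf,
                       df = n - ncol(covariates) - 1,
                       p_raw = if (d[1] == 0) 1 else 0,
                       direction = "positive t = rightward asymmetry"))
  }
  X <- scale(as.matrix(covariates), center = TRUE, scale = FALSE)
  fit <- stats::lm(d ~ X)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  stat_result("hemisphere (right - left)", "t",
              statistic = sm["(Intercept)", "t value"],
              df = fit$df.residual,
              p_raw = sm["(Intercept)", "Pr(>|t|)"],
              direction = "positive t = rightward asymmetry")
}

# assemble the analysis frame used by the group-level models
ai_frame <- function(ai, group, covariates, sex = NULL) {
  covariates <- check_covariates(covariates)
  df <- data.frame(ai = ai, group = factor(group), covariates)
  if (!is.null(sex)) df$sex <- factor(sex)
  stats::na.omit(df)
}

#' Sex-by-group interaction screen for an AI measure
#'
#' Fits the covariate-adjusted linear model of AI on group, sex, and their
#' interaction, and F-tests the interaction term. When the interaction is
#' significant at `alpha`, downstream group comparisons should be stratified
#' by sex (`stratify_by_sex` flag); otherwise the interaction term is dropped
#' and groups are compared in the pooled model.
#'
#' @param ai AI values, one per subject.
#' @param group group factor (e.g. NC/MCI/AD).
#' @param sex two-level factor; both levels must be present.
#' @param covariates data.frame of numeric covariates (age, whole-brain ICV,
#'   hemispheric-ICV difference, TR, TE).
#' @param alpha screening level (default 0.05).
#' @return a [stat_result()] with an extra `stratify_by_sex` element.
#' @export
interaction_screen <- function(ai, group, sex, covariates, alpha = 0.05) {
  sex <- factor(sex)
  if (nlevels(sex) < 2) stop("both sexes must be present")
  group <- factor(group)
  if (nlevels(group) < 2) stop("at least two groups required")
  tab <- table(group, sex)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty sex x group cell: group %s, sex %s",
                 rownames(tab)[empty[1]], colnames(tab)[empty[2]]))
  }
  df <- ai_frame(ai, group, covariates, sex)
  cv <- paste(names(covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste("ai ~ group * sex +", cv)), df)
  red <- stats::lm(stats::as.formula(paste("ai ~ group + sex +", cv)), df)
  check_full_rank(full)
  an <- stats::anova(red, full)
  res <- stat_result("sex x group interaction", "F",
                     statistic = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                     p_raw = an$`Pr(>F)`[2])
  res$stratify_by_sex <- an$`Pr(>F)`[2] < alpha
  res
}

#' Group main effect on an AI measure
#'
#' Covariate-adjusted F-test of the group factor in the linear model of AI.
#' When a sex stratum is requested, the model is fitted within that stratum
#' and sex is dropped from the covariates.
#'
#' @inheritParams interaction_screen
#' @param stratum `"all"`, or a sex level to restrict to.
#' @param sex sex vector; required when stratifying.
#' @return a [stat_result()] (F statistic).
#' @export
group_main_effect <- function(ai, group, covariates, stratum = "all",
                              sex = NULL) {
  group <- factor(group)
  if (stratum != "all") {
    if (is.null(sex)) stop("sex is required when stratifying")
    keep <- sex == stratum
    ai <- ai[keep]; group <- droplevels(group[keep])
    covariates <- covariates[keep, setdiff(names(covariates), "sex"),
                             drop = FALSE]
  }
  if (nlevels(droplevels(group)) < 2)
    stop("at least two groups required in the stratum")
  df <- ai_frame(ai, group, covariates)
  cv <- paste(setdiff(names(df), c("ai", "group")), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste("ai ~ group +", cv)), df)
  red <- stats::lm(stats::as.formula(paste("ai ~", cv)), df)
  check_full_rank(full)
  an <- stats::anova(red, full)
  stat_result(sprintf("group main effect (%s)", stratum), "F",
              statistic = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
              p_raw = an$`Pr(>F)`[2])
}

#' Pairwise post hoc group comparisons with Bonferroni correction
#'
#' Covariate-adjusted two-group t-tests for the three contrasts AD-NC,
#' AD-MCI, and MCI-NC (first minus second), each Bonferroni-corrected for
#' the three comparisons: `p_adjusted = min(1, 3 * p_raw)`.
#'
#' @inheritParams group_main_effect
#' @param pairs list of length-2 character vectors naming the contrasts;
#'   defaults to the three AD/MCI/NC pairs present in `group`.
#' @return list of three [stat_result()]s.
#' @export
posthoc_pairwise <- function(ai, group, covariates, pairs = NULL) {
  group <- as.character(group)
  if (is.null(pairs)) {
    levs <- c("AD", "MCI", "NC")
    if (!all(sort(unique(group)) == sort(levs)))
      stop("default pairs need exactly the groups AD, MCI, NC")
    pairs <- list(c("AD", "NC"), c("AD", "MCI"), c("MCI", "NC"))
  }
  m <- length(pairs)
  lapply(pairs, function(pr) {
    keep <- group %in% pr
    g <- group[keep]
    if (any(table(g) < 2))
      stop(sprintf("group with fewer than 2 members in contrast %s-%s",
                   pr[1], pr[2]))
    df <- ai_frame(ai[keep], g, covariates[keep, , drop = FALSE])
    df$ind <- as.numeric(df$group == pr[1])   # coefficient = first - second
    cv <- paste(setdiff(names(df), c("ai", "group", "ind")), collapse = " + ")
    fit <- stats::lm(stats::as.formula(paste("ai ~ ind +", cv)), df)
    check_full_rank(fit)
    sm <- summary(fit)$coefficients
    p <- sm["ind", "Pr(>|t|)"]
    stat_result(sprintf("%s - %s", pr[1], pr[2]), "t",
                statistic = sm["ind", "t value"], df = fit$df.residual,
                p_raw = p, p_adjusted = min(1, m * p),
                adjustment = "bonferroni",
                direction = sprintf("positive t = higher AI in %s", pr[1]))
  })
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`: with sorted p-values `p_(1) <= ... <=
#' p_(m)`, reject all hypotheses up to the largest `k` with
#' `p_(k) <= k * q / m`. The rejection mask is computed via BH-adjusted
#' p-values (`p.adjust`), which is equivalent to the step-up rule.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `reject` (logical mask in the original order),
#'   `critical_index` (the step-up `k`, 0 if none), `threshold` (the
#'   rejection p-value cutoff, 0 if none), and `p_adjusted`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  padj <- stats::p.adjust(p, method = "BH")
  reject <- !is.na(padj) & padj <= q
  ps <- sort(p[!is.na(p)])
  ok <- which(ps <= seq_along(ps) * q / length(ps))
  k <- if (length(ok)) max(ok) else 0L
  list(reject = reject, critical_index = k,
       threshold = if (k > 0) ps[k] else 0, p_adjusted = padj)
}

#' AI-cognitive score association regression
#'
#' Multiple linear regression of a cognitive score (e.g. a RAVLT subscore)
#' on an asymmetry index, adjusting for covariates; reports the t-test of
#' the AI coefficient. A negative t means higher rightward asymmetry is
#' associated with a lower score.
#'
#' @param ai AI values, one per subject.
#' @param score numeric score (response).
#' @param covariates data.frame of numeric covariates.
#' @return a [stat_result()] (t statistic for the AI coefficient).
#' @export
association_regression <- function(ai, score, covariates) {
  covariates <- check_covariates(covariates)
  df <- stats::na.omit(data.frame(score = score, ai = ai, covariates))
  if (nrow(df) < ncol(covariates) + 3)
    stop("too few complete cases for the association regression")
  if (stats::sd(df$score) == 0) stop("score has zero variance")
  if (stats::sd(df$ai) == 0) stop("collinear model term(s): ai is constant")
  cv <- paste(names(covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("score ~ ai +", cv)), df)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  stat_result("AI coefficient", "t", statistic = sm["ai", "t value"],
              df = fit$df.residual, p_raw = sm["ai", "Pr(>|t|)"],
              direction = "negative t = rightward asymmetry with lower score")
}
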