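# Cohort statistics: contingency tests (Unknown kept as a category by
# default), ANOVA + LSD, rank tests, survival curves, log-rank, propensity
# matching.

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; clinical tables routinely keep "Unknown" as a
#' genuine category, and callers are expected to pass it as a row unless
#' they deliberately drop it. All-zero rows/columns are dropped with a
#' warning.
#'
#' @param table r-by-c matrix of non-negative integer counts.
#' @return list `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(table) {
  if (!is.matrix(table) || any(table < 0)) abort("need a non-negative count matrix")
  zr <- rowSums(table) == 0; zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero rows/columns", call. = FALSE)
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) abort("degenerate table (< 2 rows or columns)")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than the
#' observed table's.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return list `odds_ratio` (conditional MLE), `p`.
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2, 2)))
    abort("fisher_exact requires a 2x2 table")
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' One-way ANOVA with Fisher's LSD pairwise comparisons
#'
#' Standard one-way ANOVA (F = MSB/MSW) followed by least-significant-
#' difference tests: pairwise t statistics using the pooled within-group
#' mean square with `N - g` degrees of freedom and unadjusted two-sided
#' p-values.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups, >= 2 values each).
#' @return list `F`, `df` (c(between, within)), `p`, `lsd` (data.frame
#'   `group1`, `group2`, `diff`, `t`, `p`).
#' @export
anova_lsd <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (any(table(g) < 2)) abort("each group needs >= 2 values")
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  msw <- an["Residuals", "Mean Sq"]
  if (msw == 0) abort("zero within-group variance; LSD undefined")
  dfw <- an["Residuals", "Df"]
  means <- tapply(values, g, mean); ns <- tapply(values, g, length)
  pairs <- utils::combn(levels(g), 2)
  lsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- means[[a]] - means[[b]]
    tt <- d / sqrt(msw * (1 / ns[[a]] + 1 / ns[[b]]))
    data.frame(group1 = a, group2 = b, diff = d, t = tt,
               p = 2 * stats::pt(-abs(tt), dfw))
  }))
  list(F = an["g", "F value"], df = c(between = an["g", "Df"], within = dfw),
       p = an["g", "Pr(>F)"], lsd = lsd)
}

# exact two-sided rank-sum p by enumeration of all group assignments;
# tie-safe because it permutes the observed (average) ranks themselves
wilcoxon_exact_p <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  nx <- length(x)
  idx <- utils::combn(length(r), nx)
  ws <- colSums(matrix(r[idx], nrow = nx))
  obs <- sum(r[seq_len(nx)])
  ew <- nx * (length(r) + 1) / 2
  mean(abs(ws - ew) >= abs(obs - ew) - 1e-9)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic with average ranks for ties. For small samples
#' (`n_x + n_y <= 12`) the two-sided p-value is computed by full
#' enumeration of group assignments (valid under ties); otherwise by the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list `W` (rank-sum of `x`), `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("empty input")
  r <- rank(c(x, y), ties.method = "average")
  w <- sum(r[seq_along(x)])
  if (length(x) + length(y) <= 12) {
    return(list(W = w, p = wilcoxon_exact_p(x, y), method = "exact"))
  }
  n <- length(r); nx <- length(x); ny <- length(y)
  ew <- nx * (n + 1) / 2
  ties <- table(r)
  vw <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(w - ew) - 0.5) / sqrt(vw)
  list(W = w, p = min(1, 2 * stats::pnorm(-max(z, 0))), method = "normal")
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimates per group with Greenwood standard errors and
#' median survival where attained (delegates to [survival::survfit()]).
#'
#' @param times positive survival/censoring times.
#' @param events event indicator (1 = event, 0 = censored).
#' @param groups optional group labels (single pooled curve when omitted).
#' @return list `curves` (data.frame `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, `se`), `medians` (named vector, NA when not attained,
#'   with attribute `undefined` listing groups where every subject was
#'   censored).
#' @export
kaplan_meier <- function(times, events, groups = NULL) {
  if (any(times <= 0)) abort("times must be > 0")
  if (!all(events %in% c(0, 1))) abort("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  g <- factor(groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ g)
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) rep(levels(g)[1], length(smry$time))
         else sub("^g=", "", as.character(smry$strata))
  curves <- data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
                       n_event = smry$n.event, surv = smry$surv,
                       se = smry$std.err)
  med <- summary(fit)$table
  medians <- if (is.null(dim(med))) stats::setNames(med[["median"]], levels(g)[1])
             else stats::setNames(med[, "median"], sub("^g=", "", rownames(med)))
  attr(medians, "undefined") <- names(medians)[tapply(events, g, sum) == 0]
  list(curves = curves, medians = medians)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square across distinct
#' event times (delegates to [survival::survdiff()]); df = #groups - 1.
#' Invariant to any strictly monotone rescaling of the time axis.
#'
#' @inheritParams kaplan_meier
#' @param groups group labels (>= 2 non-empty groups).
#' @return list `statistic`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need >= 2 groups")
  if (sum(events) < 1) abort("need at least one event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Propensity-score matching
#'
#' Fits a logistic propensity model (IRLS via [stats::glm()]) of treatment
#' on the covariates (categoricals one-hot encoded, "Unknown" kept as its
#' own level), then matches each treated subject greedily to the nearest
#' untreated subject on the logit propensity scale, without replacement,
#' within a caliper of `caliper_sd` standard deviations of the logit
#' propensity score. Treated subjects are processed in decreasing
#' propensity order (deterministic). Standardized mean differences of each
#' encoded covariate before and after matching are reported.
#'
#' @param covariates data.frame of covariates (numeric and/or factor).
#' @param treatment logical or 0/1 vector.
#' @param caliper_sd caliper width in logit-PS standard deviations
#'   (default 0.2).
#' @return list `pairs` (data.frame `treated`, `control` row indices),
#'   `propensity` (fitted probabilities), `smd` (data.frame `covariate`,
#'   `smd_before`, `smd_after`), `n_treated`, `n_matched`.
#' @export
propensity_match <- function(covariates, treatment, caliper_sd = 0.2) {
  tr <- as.logical(treatment)
  if (any(is.na(tr))) abort("treatment must be binary")
  x <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  dat <- data.frame(.tr = tr, x, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(.tr ~ ., data = dat, family = stats::binomial()))
  ps <- stats::fitted(fit)
  if (any(ps < 1e-8) || any(ps > 1 - 1e-8)) {
    big <- names(which.max(abs(stats::coef(fit)[-1])))
    abort("separation in the propensity model (covariate '%s')", big)
  }
  lps <- stats::qlogis(ps)
  sdl <- stats::sd(lps)
  caliper <- if (sdl == 0) Inf else caliper_sd * sdl
  treated <- which(tr)[order(-lps[tr], which(tr))]
  controls <- which(!tr)
  used <- logical(length(tr))
  pairs <- list()
  for (i in treated) {
    cand <- controls[!used[controls]]
    if (length(cand) == 0) break
    d <- abs(lps[cand] - lps[i])
    j <- cand[which.min(d)]
    if (min(d) <= caliper) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- data.frame(treated = i, control = j)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated = integer(0), control = integer(0))
  smd_of <- function(idx_t, idx_c) {
    vapply(colnames(x), function(cn) {
      mt <- mean(x[idx_t, cn]); mc <- mean(x[idx_c, cn])
      sp <- sqrt((stats::var(x[idx_t, cn]) + stats::var(x[idx_c, cn])) / 2)
      if (sp == 0) 0 else (mt - mc) / sp
    }, numeric(1))
  }
  before <- smd_of(which(tr), which(!tr))
  after <- if (nrow(pairs) > 0) smd_of(pairs$treated, pairs$control) else before * NA
  list(pairs = pairs, propensity = ps,
       smd = data.frame(covariate = colnames(x), smd_before = before,
                        smd_after = after, row.names = NULL),
       n_treated = sum(tr), n_matched = nrow(pairs))
}
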