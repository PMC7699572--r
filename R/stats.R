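## Comparison machinery for the repeated-measures design: each subject is
## measured at baseline ("00", drug A alone) and at 5/10/15 min after a drug
## change, in two imaging planes, for 9 airway measures (area/AP/TX x
## min/mean/max). The stats stage consumes only the long cohort table and is
## fully decoupled from imaging.

#' Paired baseline-vs-followup comparison with effect size
#'
#' Tests the paired differences for normality (Shapiro-Wilk); normal
#' differences get a two-sided paired t-test with its t-based 95% CI,
#' otherwise a Wilcoxon signed-rank test with the Hodges-Lehmann
#' pseudomedian CI. Cohen's d (paired) is mean(diff) / sd(diff); percent
#' change is the mean over subjects of 100 * (followup - baseline) /
#' baseline, respecting the pairing.
#'
#' @param baseline,followup equal-length paired numeric vectors, n >= 3.
#' @param normality_alpha Shapiro-Wilk level deciding t vs Wilcoxon
#'   (default 0.05).
#' @param measure label carried into the result.
#' @return One-row data.frame: measure, n, mean_base, sd_base, mean_follow,
#'   sd_follow, diff, ci_lo, ci_hi, pct_change, cohens_d, test
#'   ("paired-t" or "wilcoxon"), p.
#' @details Subjects with baseline exactly 0 are excluded from the percent
#'   change (with a warning); identically zero differences give p = 1,
#'   d = 0.
#' @examples
#' set.seed(1)
#' base <- rnorm(22, 100, 15)
#' pairedCompare(base, base + rnorm(22, 0, 5), measure = "area_mean")
#' @export
pairedCompare <- function(baseline, followup, normality_alpha = 0.05,
                          measure = "measure") {
  stopifnot(length(baseline) == length(followup))
  keep <- complete.cases(baseline, followup)
  baseline <- baseline[keep]; followup <- followup[keep]
  n <- length(baseline)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- followup - baseline
  ok0 <- baseline != 0
  if (!all(ok0))
    warning(sum(!ok0), " subject(s) with baseline 0 excluded from percent change")
  pct <- if (any(ok0)) mean(100 * d[ok0] / baseline[ok0]) else NA_real_
  if (all(d == 0)) {
    return(data.frame(measure = measure, n = n,
                      mean_base = mean(baseline), sd_base = sd(baseline),
                      mean_follow = mean(followup), sd_follow = sd(followup),
                      diff = 0, ci_lo = 0, ci_hi = 0, pct_change = pct,
                      cohens_d = 0, test = "paired-t", p = 1))
  }
  if (sd(d) == 0) {
    ## constant nonzero difference: a deterministic shift
    return(data.frame(measure = measure, n = n,
                      mean_base = mean(baseline), sd_base = sd(baseline),
                      mean_follow = mean(followup), sd_follow = sd(followup),
                      diff = mean(d), ci_lo = mean(d), ci_hi = mean(d),
                      pct_change = pct, cohens_d = sign(mean(d)) * Inf,
                      test = "paired-t", p = 0))
  }
  normal <- shapiro.test(d)$p.value >= normality_alpha
  if (normal) {
    tt <- t.test(d, conf.level = 0.95)
    ci <- as.numeric(tt$conf.int); p <- tt$p.value; test <- "paired-t"
  } else {
    wt <- suppressWarnings(wilcox.test(d, conf.int = TRUE, conf.level = 0.95,
                                       exact = FALSE))
    ci <- as.numeric(wt$conf.int); p <- wt$p.value; test <- "wilcoxon"
  }
  data.frame(measure = measure, n = n,
             mean_base = mean(baseline), sd_base = sd(baseline),
             mean_follow = mean(followup), sd_follow = sd(followup),
             diff = mean(d), ci_lo = ci[1L], ci_hi = ci[2L],
             pct_change = pct, cohens_d = mean(d) / sd(d),
             test = test, p = p)
}

#' Linear mixed-effects dose-response model for one airway measure
#'
#' Models each subject's change from baseline at the post-baseline time
#' levels: `change ~ time + age + baseline + (1 | subject)`, fit by REML with
#' Satterthwaite degrees of freedom. Reports least-squares means of the
#' change per time level (covariates at their means) with 95% CIs and raw
#' p-values against zero change. A singular or failed random-intercept fit
#' is downgraded to a fixed-effects-only linear model, flagged in the
#' result, never silently ignored.
#'
#' @param cohort long cohort table with columns subject, plane, condition,
#'   measure, value, age (see [makeCohort()]); the first factor level of
#'   `condition` (or `"00"` if present) is the baseline.
#' @param measure measure label to model, e.g. `"area_mean"`.
#' @param plane optional plane filter (`"NP"`, `"RG"`); `NULL` uses all rows
#'   of the measure (planes pooled — supply a plane for the per-plane models).
#' @return list with `lsm` (data.frame: measure, time, estimate, ci_lo,
#'   ci_hi, p), `fit` (the model object), `converged` and `random_dropped`
#'   flags.
#' @examples
#' tab <- makeCohort(cohortSpec(n_subjects = 8, seed = 4),
#'                   phantomSpec(n_frames = 6), images = FALSE,
#'                   measurement_cv = 0.05)$truth
#' fitLmm(tab, "area_mean", plane = "NP")$lsm
#' @export
fitLmm <- function(cohort, measure, plane = NULL) {
  tab <- cohort[cohort$measure == measure, , drop = FALSE]
  if (!is.null(plane)) tab <- tab[tab$plane == plane, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for measure ", measure)
  condLevels <- unique(tab$condition)
  baselineLevel <- if ("00" %in% condLevels) "00" else condLevels[1L]
  base <- tab[tab$condition == baselineLevel, c("subject", "plane", "value")]
  names(base)[3L] <- "baseline"
  fu <- tab[tab$condition != baselineLevel, , drop = FALSE]
  dat <- merge(fu, base, by = c("subject", "plane"))
  if (nrow(dat) == 0L) stop("no post-baseline rows for measure ", measure)
  dat$change <- dat$value - dat$baseline
  dat$time <- factor(dat$condition,
                     levels = setdiff(condLevels, baselineLevel))
  dat$subject <- factor(dat$subject)
  if (sum(table(dat$subject) >= 2L) < 2L)
    stop("need >= 2 subjects with >= 2 time levels each")
  random_dropped <- FALSE; converged <- TRUE
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      change ~ time + age + baseline + (1 | subject), data = dat,
      REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    if (!is.null(fit)) random_dropped <- TRUE
    fitLm <- lm(change ~ time + age + baseline, data = dat)
    if (is.null(fit)) { converged <- FALSE; random_dropped <- TRUE }
    fit <- fitLm
  }
  em <- emmeans::emmeans(fit, ~time, lmer.df = "satterthwaite")
  es <- as.data.frame(summary(em, infer = c(TRUE, TRUE), null = 0))
  ciCols <- intersect(c("lower.CL", "asymp.LCL"), names(es))[1L]
  chCols <- intersect(c("upper.CL", "asymp.UCL"), names(es))[1L]
  lsm <- data.frame(measure = measure,
                    time = as.character(es$time),
                    estimate = es$emmean,
                    ci_lo = es[[ciCols]], ci_hi = es[[chCols]],
                    p = es$p.value)
  list(lsm = lsm, fit = fit, converged = converged,
       random_dropped = random_dropped)
}

#' Family-wise multiplicity adjustment
#'
#' Bonferroni (default) or Holm over the p-value family supplied by the
#' caller — in the standard pipeline, the full set of airway measures.
#' Adjusted values are monotone and never below the raw values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' multiplicityAdjust(c(0.0184), method = "bonferroni")  # singleton: unchanged
#' multiplicityAdjust(rep(0.0184, 24))[1]                # 24-family: 0.4416
#' @export
multiplicityAdjust <- function(p, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric())
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))   # NA = degenerate fit
  p.adjust(p, method = method)
}

#' Dunnett-adjusted many-to-one comparisons against baseline
#'
#' Paired comparisons of each time level against the control/baseline level
#' within a repeated-measures design. Per level, the statistic is the paired
#' t statistic of the differences; the family-wise adjustment uses the exact
#' joint distribution of the comparison set — central multivariate t with
#' n - 1 degrees of freedom and the empirical correlation of the per-subject
#' difference vectors: `p_adj_j = 1 - P(max_k |T_k| <= |t_j|)`.
#'
#' @param baseline numeric vector, one value per subject (the control level).
#' @param followups matrix or data.frame, subjects x time levels, or a single
#'   vector for one level.
#' @return data.frame: time, n, mean_diff, t, p_raw, p_adj. With a single
#'   comparison the adjusted p equals the unadjusted paired-t p.
#' @details The multivariate-t integral is evaluated with mvtnorm's
#'   quasi-Monte-Carlo algorithm under a pinned internal RNG state, so
#'   results are deterministic and the caller's random stream is untouched.
#'   Degenerate zero-variance differences give t = 0 (and p = 1) when the
#'   mean difference is zero, and p approaching 0 otherwise.
#' @examples
#' set.seed(2)
#' base <- rnorm(22, 100, 15)
#' fu <- cbind(t5 = base + rnorm(22, 0, 8), t10 = base + rnorm(22, 0, 8),
#'             t15 = base + rnorm(22, 0, 8))
#' dunnettCompare(base, fu)
#' @export
dunnettCompare <- function(baseline, followups) {
  if (is.null(dim(followups))) followups <- cbind(t1 = followups)
  followups <- as.matrix(followups)
  k <- ncol(followups)
  if (k == 0L) stop("no time levels to compare")
  stopifnot(nrow(followups) == length(baseline))
  D <- followups - baseline
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 subjects")
  mu <- colMeans(D)
  s <- apply(D, 2L, sd)
  tstat <- ifelse(s > 0, mu / (s / sqrt(n)),
                  ifelse(mu == 0, 0, sign(mu) * Inf))
  praw <- 2 * pt(-abs(tstat), df = n - 1L)
  if (k == 1L) {
    padj <- praw
  } else {
    R <- suppressWarnings(cor(D))
    R[!is.finite(R)] <- 0; diag(R) <- 1
    ## pin the RNG so the QMC integral is reproducible call-to-call
    hasSeed <- exists(".Random.seed", envir = globalenv())
    if (hasSeed) oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (hasSeed) assign(".Random.seed", oldSeed, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(190561L)
    padj <- vapply(abs(tstat), function(tj) {
      if (!is.finite(tj)) return(0)
      pr <- mvtnorm::pmvt(lower = rep(-tj, k), upper = rep(tj, k),
                          df = n - 1L, corr = R,
                          algorithm = mvtnorm::GenzBretz(abseps = 1e-4,
                                                         maxpts = 25000L))
      max(0, 1 - as.numeric(pr))
    }, 0)
  }
  data.frame(time = colnames(followups) %||% paste0("t", seq_len(k)),
             n = n, mean_diff = mu, t = tstat,
             p_raw = praw, p_adj = pmax(padj, praw), row.names = NULL)
}

#' Cohort-wide paired comparison across all measures
#'
#' Runs [pairedCompare()] (baseline vs a chosen follow-up condition) for
#' every (plane, measure) cell of a long cohort table and appends
#' family-adjusted p-values over the full set.
#'
#' @param cohort long cohort table (subject, plane, condition, measure,
#'   value, age).
#' @param followup condition label compared against baseline (default "15").
#' @param baseline baseline condition label (default "00").
#' @param adjust multiplicity method for the family of all rows.
#' @return data.frame with one row per plane x measure:
#'   measure (prefixed by plane), n, mean_base, sd_base, mean_follow,
#'   sd_follow, diff, ci_lo, ci_hi, pct_change, cohens_d, test, p_raw, p_adj.
#' @export
cohortCompare <- function(cohort, followup = "15", baseline = "00",
                          adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  cells <- unique(cohort[, c("plane", "measure")])
  cells <- cells[order(cells$plane, cells$measure), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- cohort[cohort$plane == cells$plane[i] &
                  cohort$measure == cells$measure[i], , drop = FALSE]
    b <- sub[sub$condition == baseline, c("subject", "value")]
    f <- sub[sub$condition == followup, c("subject", "value")]
    m <- merge(b, f, by = "subject", suffixes = c("_b", "_f"))
    pairedCompare(m$value_b, m$value_f,
                  measure = paste(cells$plane[i], cells$measure[i], sep = "_"))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "p"] <- "p_raw"
  out$p_adj <- multiplicityAdjust(out$p_raw, method = adjust)
  out
}

#' Mixed-model dose-response across all measures
#'
#' Runs [fitLmm()] per (plane, measure) cell and adjusts the pooled p-value
#' family (all cells x time levels).
#'
#' @inheritParams cohortCompare
#' @return data.frame: measure, time, estimate, ci_lo, ci_hi, p_raw, p_adj,
#'   random_dropped.
#' @export
cohortLmm <- function(cohort, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  cells <- unique(cohort[, c("plane", "measure")])
  cells <- cells[order(cells$plane, cells$measure), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    res <- fitLmm(cohort, cells$measure[i], plane = cells$plane[i])
    lsm <- res$lsm
    lsm$measure <- paste(cells$plane[i], cells$measure[i], sep = "_")
    lsm$random_dropped <- res$random_dropped
    lsm
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "p"] <- "p_raw"
  out$p_adj <- multiplicityAdjust(out$p_raw, method = adjust)
  out
}
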