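#' One-way ANOVA
#'
#' Classical between/within variance decomposition with the p-value from the
#' F distribution; used both to compare repeated-run performance between two
#' models and to test feature-label associations.
#'
#' @param groups list of numeric vectors (>= 2 groups, each of size >= 2).
#' @return List with `F`, `p`, `df1`, `df2`; `flag` is `"degenerate"` when
#'   the within-group variance is zero while between-group variance is not
#'   (F infinite, p reported as 0).
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("one_way_anova: every group needs >= 2 values")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(x) == 0) return(list(F = 0, p = 1, df1 = nlevels(g) - 1,
                                      df2 = length(x) - nlevels(g), flag = NULL))
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0.0) - mean(x))^2)
  df1 <- length(groups) - 1
  df2 <- length(x) - length(groups)
  if (ssw == 0)
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2, flag = "degenerate"))
  Fs <- (ssb / df1) / (ssw / df2)
  list(F = Fs, p = stats::pf(Fs, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, flag = NULL)
}

#' Association between a feature and a binary label
#'
#' One-way ANOVA of the feature across the label groups.
#'
#' @param values numeric feature values.
#' @param labels binary labels (both classes present).
#' @return List as [one_way_anova()].
#' @export
feature_association <- function(values, labels) {
  labels <- as.character(labels)
  cls <- unique(labels[!is.na(labels)])
  if (length(cls) < 2) stop("feature_association: both classes required")
  one_way_anova(split(values, labels))
}

#' Kaplan-Meier comparison of a median split of a feature
#'
#' The covariate is standardized and split at its median (ties go to the
#' lower group); the two groups are compared with product-limit survival
#' curves and the unweighted two-group log-rank test. The likelihood-ratio
#' p-value of the corresponding two-group Cox model is reported alongside.
#'
#' @param time survival times (months); @param event 1 = death, 0 = censored.
#' @param covariate numeric feature per case.
#' @return List: `fit` (a `survfit` object), `median_survival` per group,
#'   `chisq`, `p` (log-rank), `p_lr` (likelihood ratio), `group` factor.
#' @export
km_logrank_median_split <- function(time, event, covariate) {
  z <- (covariate - mean(covariate)) / stats::sd(covariate)
  grp <- factor(ifelse(z <= stats::median(z), "low", "high"), c("low", "high"))
  if (any(table(grp) < 2)) stop("km_logrank_median_split: degenerate split")
  d <- data.frame(time = time, event = event, group = grp)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chisq <- sd_$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group, data = d)
  p_lr <- stats::pchisq(2 * (cx$loglik[2] - cx$loglik[1]), df = 1,
                        lower.tail = FALSE)
  med <- summary(fit)$table
  med_col <- if (is.matrix(med)) med[, "median"] else med[["median"]]
  list(fit = fit, median_survival = med_col, chisq = chisq, p = p,
       p_lr = p_lr, group = grp)
}

#' Cox hazard ratio per standard deviation of a feature
#'
#' The covariate is standardized to unit SD; a univariate proportional-
#' hazards model gives HR = exp(beta) per SD, a Wald 95% CI from the observed
#' information, and a likelihood-ratio p-value. A one-SD increase multiplies
#' the hazard by HR, i.e. changes the risk by (HR - 1) x 100%.
#'
#' @param time,event survival data (>= 1 event).
#' @param covariate numeric feature with positive variance.
#' @return List: `hr`, `ci` (length 2), `beta`, `se`, `p_lr`, `flag`
#'   (`"monotone_likelihood"` on perfect separation).
#' @export
cox_per_sd <- function(time, event, covariate) {
  if (stats::sd(covariate) == 0) stop("cox_per_sd: constant covariate")
  if (sum(event) < 1) stop("cox_per_sd: no events")
  z <- (covariate - mean(covariate)) / stats::sd(covariate)
  fit <- survival::coxph(survival::Surv(time, event) ~ z)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  p_lr <- stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]), df = 1,
                        lower.tail = FALSE)
  flag <- if (abs(beta) > 15) "monotone_likelihood" else NULL
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       beta = beta, se = se, p_lr = p_lr, flag = flag)
}

#' Feature-count sweep of inner cross-validated AUC
#'
#' Aggregates the per-size inner LOOCV AUCs across repetitions into the mean
#' and a two-standard-deviation band per candidate size.
#'
#' @param result a `model_run_result` from [run_repetitions()], or a numeric
#'   matrix repetitions x sizes (named columns).
#' @param variant which variant's sweep to aggregate.
#' @return Data frame: `size`, `mean_auc`, `two_sd` (NA with a flag when only
#'   one repetition is available).
#' @export
feature_count_sweep <- function(result, variant = "with_fractal") {
  if (inherits(result, "model_run_result")) {
    rows <- Filter(function(s) s[["variant"]] == variant, result$sweep)
    m <- do.call(rbind, lapply(rows, function(s) {
      as.numeric(s[setdiff(names(s), c("repetition", "variant"))])
    }))
    colnames(m) <- setdiff(names(result$sweep[[1]]), c("repetition", "variant"))
  } else m <- result
  out <- data.frame(size = as.integer(colnames(m)),
                    mean_auc = colMeans(m),
                    two_sd = if (nrow(m) >= 2) 2 * apply(m, 2, stats::sd)
                             else NA_real_)
  rownames(out) <- NULL
  attr(out, "flag") <- if (nrow(m) < 2) "single_repetition" else NULL
  out
}

#' Compare two repeated-run metric samples
#'
#' ANOVA (as in the with/without-fractal model comparison) plus, since the
#' repetitions are paired by partition, a paired t-test for reference.
#'
#' @param a,b numeric metric vectors (e.g. test AUC per repetition).
#' @return List: `anova` ([one_way_anova()] result), `paired_p` (or NA if
#'   lengths differ).
#' @export
compare_model_runs <- function(a, b) {
  res <- if (length(a) >= 2 && length(b) >= 2) one_way_anova(list(a, b)) else NULL
  paired_p <- if (length(a) == length(b) && length(a) >= 2 &&
                  isTRUE(stats::sd(a - b) > 0))
    stats::t.test(a, b, paired = TRUE)$p.value else NA_real_
  list(anova = res, paired_p = paired_p)
}
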