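# Statistical evaluation layer: precision-recall curves, simulated curator
# panels with consensus, one-sample and paired hypothesis tests against the
# 50% chance baseline, and pre/post-treatment area-trajectory analysis with
# Monte-Carlo Dunnett-style comparisons.

#' Precision-recall curve and area under it
#'
#' Precision and recall are computed at every distinct score threshold
#' (descending); the area is the step-wise integral
#' `sum((R_i - R_{i-1}) * P_i)`.  A binary 0/1 rater yields its single
#' operating point.
#'
#' @param scores numeric scores (higher = more confident dead)
#' @param labels 0/1 truth vector
#' @return object of class `pr_curve`: `points` (data frame with threshold,
#'   recall, precision), `auprc`
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  P <- sum(y == 1)
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each distinct score
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  precision <- tp / (tp + fp)
  recall <- tp / P
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(threshold = thr, recall = recall,
                                     precision = precision),
                 auprc = auprc),
            class = "pr_curve")
}

#' Define a simulated curator
#'
#' A stochastic rater standing in for a human curator, characterized by
#' sensitivity (probability of calling a dead cell dead) and specificity
#' (probability of calling a live cell live).
#'
#' @param name label
#' @param sensitivity,specificity in \[0, 1\]
#' @return list of class `curator_profile`
#' @export
curator_profile <- function(name, sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity),
            class = "curator_profile")
}

#' Simulate curator calls and their consensus
#'
#' Each curator calls each cell independently according to their profile; the
#' consensus is the majority vote with ties resolved toward dead (flagged).
#'
#' @param labels 0/1 truth vector
#' @param profiles list of [curator_profile()]s
#' @param seed RNG seed
#' @return list with `calls` (n x k 0/1 matrix), `consensus` (0/1 vector),
#'   `tie_flag` (TRUE where a tie was broken)
#' @export
simulate_curators <- function(labels, profiles, seed = 1L) {
  if (length(labels) == 0) stop("empty batch")
  stopifnot(length(profiles) >= 1)
  labels <- as.integer(labels)
  n <- length(labels)
  with_seed(seed, {
    calls <- vapply(profiles, function(p) {
      p_dead <- ifelse(labels == 1, p$sensitivity, 1 - p$specificity)
      as.integer(stats::runif(n) < p_dead)
    }, integer(n))
    calls <- matrix(calls, nrow = n)
  })
  votes <- rowSums(calls)
  k <- length(profiles)
  consensus <- as.integer(votes >= k / 2)  # ties (votes == k/2) -> dead
  tie_flag <- votes * 2 == k
  colnames(calls) <- vapply(profiles, `[[`, "", "name")
  list(calls = calls, consensus = consensus, tie_flag = tie_flag)
}

#' One-sample tests against a chance-level mean
#'
#' One-sample t test plus Wilcoxon signed-rank (exact for n <= 25, normal
#' approximation above), two-sided, as used to compare batch accuracies to
#' the theoretical 50% chance mean.
#'
#' @param x numeric vector (e.g. batch accuracies in percent)
#' @param mu null mean (default 50)
#' @return list of two `test_result`s (`t`, `wilcoxon`), each with
#'   `statistic`, `p_value`, `test`, `n`, `flag`
#' @export
one_sample_tests <- function(x, mu = 50) {
  n <- length(x)
  if (n < 2) stop("need at least 2 values for the one-sample t test")
  if (stats::sd(x) == 0) {
    flag <- "zero variance"
    tt <- list(statistic = NA_real_, p_value = 1, test = "one-sample t",
               n = n, flag = flag)
  } else {
    t0 <- stats::t.test(x, mu = mu)
    tt <- list(statistic = unname(t0$statistic), p_value = t0$p.value,
               test = "one-sample t", n = n, flag = NA_character_)
  }
  nz <- x[x != mu]
  if (length(nz) == 0) {
    wt <- list(statistic = NA_real_, p_value = 1, test = "wilcoxon signed-rank",
               n = n, flag = "all values equal mu")
  } else {
    w0 <- suppressWarnings(
      stats::wilcox.test(x, mu = mu, exact = length(nz) <= 25,
                         correct = TRUE))
    wt <- list(statistic = unname(w0$statistic), p_value = w0$p.value,
               test = "wilcoxon signed-rank", n = n, flag = NA_character_)
  }
  list(t = structure(tt, class = "test_result"),
       wilcoxon = structure(wt, class = "test_result"))
}

#' Paired t test between matched batch accuracies
#'
#' @param a,b equal-length paired numeric vectors (e.g. model vs curator
#'   accuracy per batch)
#' @return `test_result` with `statistic`, `p_value`, `n`, `flag`
#'   (`"zero variance"` when the differences are constant and nonzero)
#' @export
paired_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(structure(list(statistic = 0, p_value = 1, test = "paired t",
                            n = length(d), flag = NA_character_),
                       class = "test_result"))
    }
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          test = "paired t", n = length(d),
                          flag = "zero variance"),
                     class = "test_result"))
  }
  t0 <- stats::t.test(a, b, paired = TRUE)
  structure(list(statistic = unname(t0$statistic), p_value = t0$p.value,
                 test = "paired t", n = length(d), flag = NA_character_),
            class = "test_result")
}

#' Monte-Carlo critical value for Dunnett-style comparisons
#'
#' Simulates the null distribution of `max_i |t_i|` over `k` treatment-vs-
#' control contrasts with a pooled variance estimate, and returns the
#' `1 - alpha` quantile.  Group sizes may differ; `n` recycles.
#'
#' @param k number of treatment groups (comparisons against control)
#' @param n per-group sample size (control listed first if length k + 1)
#' @param alpha significance level
#' @param ndraws Monte-Carlo draws
#' @param seed RNG seed
#' @return critical value (scalar)
#' @export
dunnett_mc_crit <- function(k, n, alpha = 0.05, ndraws = 100000L, seed = 1L) {
  ns <- rep_len(n, k + 1)
  df <- sum(ns) - (k + 1)
  with_seed(seed, {
    m0 <- stats::rnorm(ndraws, 0, sqrt(1 / ns[1]))
    s2 <- stats::rchisq(ndraws, df) / df
    maxt <- rep(0, ndraws)
    for (i in seq_len(k)) {
      mi <- stats::rnorm(ndraws, 0, sqrt(1 / ns[i + 1]))
      ti <- abs(mi - m0) / sqrt(s2 * (1 / ns[i + 1] + 1 / ns[1]))
      maxt <- pmax(maxt, ti)
    }
    unname(stats::quantile(maxt, 1 - alpha))
  })
}

#' Area-trajectory analysis with Dunnett-style comparisons
#'
#' Tests whether mean fluorescent area changes after treatment: one-way
#' ANOVA across timepoints plus comparisons of every post-treatment
#' timepoint against the pretreatment group, using t statistics with a
#' pooled variance and Monte-Carlo max-|t| critical values (the Dunnett
#' family correction).  Also reports the post/pre mean-area ratio and the
#' direction of change.
#'
#' @param areas data frame with columns `track_id`, `timepoint_h`, `area_px`
#' @param pre_timepoint the pretreatment timepoint (default: the minimum)
#' @param alpha family-wise significance level
#' @param ndraws Monte-Carlo draws for the critical value
#' @param seed RNG seed
#' @return list with `anova` (`test_result` with F statistic), `dunnett`
#'   (data frame: timepoint_h, mean_area, t, significant), `crit`,
#'   `ratio` (mean post area / mean pre area), `direction`
#' @export
area_trajectory_test <- function(areas, pre_timepoint = NULL, alpha = 0.01,
                                 ndraws = 100000L, seed = 1L) {
  stopifnot(all(c("track_id", "timepoint_h", "area_px") %in% names(areas)))
  tps <- sort(unique(areas$timepoint_h))
  if (length(tps) < 2) stop("need at least 2 timepoints")
  pre <- pre_timepoint %||% min(tps)
  if (!pre %in% tps) stop("pretreatment timepoint absent from the data")
  grp <- factor(areas$timepoint_h, levels = tps)
  if (min(table(grp)) < 3) stop("need >= 3 cells per timepoint")

  means <- tapply(areas$area_px, grp, mean)
  ns <- tapply(areas$area_px, grp, length)
  vars <- tapply(areas$area_px, grp, stats::var)
  k_all <- length(tps)
  df <- sum(ns) - k_all
  sp2 <- sum((ns - 1) * vars) / df
  gm <- mean(areas$area_px)
  ssb <- sum(ns * (means - gm)^2)
  Fstat <- if (sp2 > 0) (ssb / (k_all - 1)) / sp2 else 0
  p_anova <- if (sp2 > 0) stats::pf(Fstat, k_all - 1, df, lower.tail = FALSE)
             else 1
  anova_res <- structure(list(statistic = Fstat, p_value = p_anova,
                              test = "one-way ANOVA", n = nrow(areas),
                              flag = if (sp2 == 0) "zero variance"
                                     else NA_character_),
                         class = "test_result")

  post <- setdiff(tps, pre)
  pre_i <- match(pre, tps)
  tstats <- vapply(post, function(tp) {
    i <- match(tp, tps)
    if (sp2 == 0) return(0)
    (means[i] - means[pre_i]) / sqrt(sp2 * (1 / ns[i] + 1 / ns[pre_i]))
  }, 0)
  crit <- dunnett_mc_crit(length(post), n = round(mean(ns)), alpha = alpha,
                          ndraws = ndraws, seed = seed)
  dn <- data.frame(timepoint_h = post, mean_area = as.numeric(means[match(post, tps)]),
                   t = as.numeric(tstats),
                   significant = abs(tstats) > crit)
  ratio <- mean(areas$area_px[areas$timepoint_h != pre]) /
    mean(areas$area_px[areas$timepoint_h == pre])
  list(anova = anova_res, dunnett = dn, crit = crit, ratio = ratio,
       direction = if (ratio > 1) "increase" else if (ratio < 1) "decrease"
                   else "none",
       pre_mean = as.numeric(means[pre_i]))
}
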