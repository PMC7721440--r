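# The study-style statistical battery: Grubbs outlier screening, one-way
# ANOVA with Tukey-Kramer post hoc, pooled-variance Student t, two-way
# repeated-measures (split-plot) ANOVA, Pearson correlation panels, and the
# scalar derived measures (water-maze blocks, DMP improvement, 2^-ddCt,
# densitometry fold change). Standard tests are delegated to base stats
# (oneway.test, aov, t.test, cor.test); alpha = 0.05 conventions throughout.

split_feature <- function(table, feature) {
  if (!feature %in% names(table))
    stop("feature '", feature, "' not found in table", call. = FALSE)
  if (!"group" %in% names(table))
    stop("table must have a 'group' column", call. = FALSE)
  split(table[[feature]], table$group)
}

#' Grubbs outlier screening per group
#'
#' Two-sided Grubbs test applied once per group (no iterative re-testing):
#' `G = max|x - mean| / SD` is compared with the critical value
#' `G_crit = ((N-1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2))` where `t` is the
#' upper `alpha/(2N)` quantile of the t distribution with `N-2` df. At most
#' the single most extreme value per group is flagged.
#'
#' @param values A named list of numeric vectors (one per group), or a
#'   data.frame with `group` plus a feature column named by `feature`.
#' @param alpha Significance level (default 0.05).
#' @param feature Feature column when `values` is a data.frame.
#' @return A data.frame (class `grubbs_report`) with one row per group:
#'   `group`, `n`, `g`, `g_crit`, `outlier_index`, `outlier_value`,
#'   `excluded`.
#' @export
grubbs_screen <- function(values, alpha = 0.05, feature = NULL) {
  if (is.data.frame(values)) values <- split_feature(values, feature)
  rows <- lapply(names(values), function(g) {
    x <- values[[g]]
    n <- length(x)
    if (n < 3) stop("grubbs_screen: group '", g, "' has n < 3", call. = FALSE)
    s <- sd(x)
    if (s == 0) {
      warning("grubbs_screen: group '", g,
              "' has zero SD; G undefined, no exclusion", call. = FALSE)
      return(data.frame(group = g, n = n, g = NA_real_, g_crit = NA_real_,
                        outlier_index = NA_integer_, outlier_value = NA_real_,
                        excluded = FALSE, stringsAsFactors = FALSE))
    }
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    tq <- qt(1 - alpha / (2 * n), n - 2)
    g_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
    data.frame(group = g, n = n, g = G, g_crit = g_crit,
               outlier_index = if (G > g_crit) i else NA_integer_,
               outlier_value = if (G > g_crit) x[i] else NA_real_,
               excluded = G > g_crit, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("grubbs_report", "data.frame"))
}

#' Drop Grubbs-flagged outliers from a grouped table
#'
#' @param table data.frame with `group` and the feature column.
#' @param feature Feature name.
#' @param alpha Grubbs significance level.
#' @return The table with at most one row removed per group; the
#'   `grubbs_report` is attached as attribute `"screen"`.
#' @export
apply_grubbs <- function(table, feature, alpha = 0.05) {
  rep <- grubbs_screen(table, alpha = alpha, feature = feature)
  drop <- logical(nrow(table))
  for (k in which(rep$excluded)) {
    g <- rep$group[k]
    idx <- which(table$group == g)
    drop[idx[rep$outlier_index[k]]] <- TRUE
  }
  out <- table[!drop, , drop = FALSE]
  attr(out, "screen") <- rep
  out
}

#' One-way ANOVA on a grouped feature
#'
#' Classical between/within decomposition (equal-variance F test, via
#' `stats::oneway.test(var.equal = TRUE)`), with per-group means and SEMs.
#'
#' @param table data.frame with columns `group` and `feature`.
#' @param feature Feature column name.
#' @return List (class `anova_result`) with `f`, `df_between`, `df_within`,
#'   `p`, and `groups` (data.frame of n/mean/sem per group).
#' @export
one_way_anova <- function(table, feature) {
  byg <- split_feature(table, feature)
  if (length(byg) < 2) stop("one_way_anova: need >= 2 groups", call. = FALSE)
  ns <- lengths(byg)
  if (any(ns < 2))
    stop("one_way_anova: group(s) with n < 2: ",
         paste(names(byg)[ns < 2], collapse = ", "), call. = FALSE)
  ow <- oneway.test(stats::reformulate("group", feature), data = table,
                    var.equal = TRUE)
  f <- unname(ow$statistic)
  if (!is.finite(f)) { # zero within- and between-group variance
    f <- 0; p <- 1
  } else p <- unname(ow$p.value)
  groups <- data.frame(
    group = names(byg), n = as.integer(ns),
    mean = vapply(byg, mean, numeric(1)),
    sem = vapply(byg, function(x) sd(x) / sqrt(length(x)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(f = f, df_between = unname(ow$parameter[1]),
                 df_within = unname(ow$parameter[2]), p = p, groups = groups),
            class = "anova_result")
}

#' Tukey-Kramer post-hoc comparisons
#'
#' All pairwise comparisons after a one-way ANOVA, using the
#' studentized-range distribution with the within-group df; the
#' Tukey-Kramer standard error accommodates unequal n.
#'
#' @inheritParams one_way_anova
#' @return data.frame (class `tukey_result`) with one row per pair:
#'   `group1`, `group2`, `diff` (mean of group2 minus group1), `q`, `p_adj`.
#' @export
tukey_hsd <- function(table, feature) {
  byg <- split_feature(table, feature)
  if (length(byg) < 2) stop("tukey_hsd: need >= 2 groups", call. = FALSE)
  ns <- lengths(byg)
  if (any(ns < 2))
    stop("tukey_hsd: group(s) with n < 2", call. = FALSE)
  k <- length(byg)
  means <- vapply(byg, mean, numeric(1))
  df_w <- sum(ns) - k
  msw <- sum(vapply(byg, function(x) sum((x - mean(x))^2), numeric(1))) / df_w
  pairs <- utils::combn(names(byg), 2)
  rows <- apply(pairs, 2, function(pr) {
    n1 <- ns[[pr[1]]]; n2 <- ns[[pr[2]]]
    d <- means[[pr[2]]] - means[[pr[1]]]
    se <- sqrt(msw / 2 * (1 / n1 + 1 / n2))
    q <- if (se > 0) abs(d) / se else 0
    p <- if (se > 0) ptukey(q, k, df_w, lower.tail = FALSE) else 1
    data.frame(group1 = pr[1], group2 = pr[2], diff = d, q = q, p_adj = p,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("tukey_result", "data.frame"))
}

#' Pooled-variance Student's t test (two-sided)
#'
#' @param x,y Numeric vectors, each with n >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
students_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("students_t: need n >= 2 in each sample", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  tt <- t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Two-way repeated-measures (split-plot) ANOVA
#'
#' Univariate split-plot decomposition for a complete design with subjects
#' nested in groups and observed at every within-subject level: the
#' between-subjects factor is tested against the subject-within-group error
#' stratum, the within factor and the interaction against the within-subject
#' residual. No sphericity correction is applied by default;
#' `gg_correction = TRUE` applies Greenhouse-Geisser epsilon to the within
#' and interaction p values.
#'
#' @param table data.frame with columns `subject`, `group`, the within
#'   factor, and the feature.
#' @param feature Feature column name.
#' @param within Name of the within-subject factor column (e.g. `"day"`).
#' @param gg_correction Apply Greenhouse-Geisser correction to within-factor
#'   p values.
#' @return List (class `rm_anova_result`) with elements `group`, `within`,
#'   `interaction`, each a list of `f`, `df1`, `df2`, `p`.
#' @export
rm_anova_two_way <- function(table, feature, within = "day",
                             gg_correction = FALSE) {
  need <- c("subject", "group", within, feature)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("rm_anova_two_way: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- data.frame(subject = factor(table$subject),
                    group = factor(table$group),
                    w = factor(table[[within]]),
                    y = table[[feature]])
  cells <- table(tab$subject, tab$w)
  if (any(cells != 1)) {
    bad <- which(cells != 1, arr.ind = TRUE)
    stop("rm_anova_two_way: incomplete design; missing/duplicated cells: ",
         paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  fit <- aov(y ~ group * w + Error(subject), data = tab)
  sm <- summary(fit)
  sub_tab <- sm[["Error: subject"]][[1]]
  win_tab <- sm[["Error: Within"]][[1]]
  # sums of squares at the rounding floor of the response are treated as 0
  # (constant data would otherwise give 0/0)
  tol_ss <- (1e-8 * (sum(abs(tab$y)) + 1))^2
  pick <- function(tab, term, df2) {
    i <- trimws(rownames(tab)) == term
    ss <- tab[i, "Sum Sq"]; df1 <- tab[i, "Df"]
    f <- tab[i, "F value"]
    if (ss <= tol_ss) { # no effect: F defined as 0 even when the error MS is 0
      f <- 0; p <- 1
    } else p <- pf(f, df1, df2, lower.tail = FALSE)
    list(f = unname(f), df1 = unname(df1), df2 = df2, p = unname(p))
  }
  df_sub <- sub_tab[nrow(sub_tab), "Df"]
  df_win <- win_tab[nrow(win_tab), "Df"]
  res <- list(group = pick(sub_tab, "group", df_sub),
              within = pick(win_tab, "w", df_win),
              interaction = pick(win_tab, "group:w", df_win))
  if (gg_correction) {
    eps <- gg_epsilon(tab)
    for (term in c("within", "interaction")) {
      r <- res[[term]]
      res[[term]]$p <- pf(r$f, r$df1 * eps, r$df2 * eps, lower.tail = FALSE)
      res[[term]]$gg_epsilon <- eps
    }
  }
  structure(res, class = "rm_anova_result")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# subject x within-level matrix.
gg_epsilon <- function(tab) {
  wide <- tapply(tab$y, list(tab$subject, tab$w), mean)
  grp <- tab$group[match(rownames(wide), tab$subject)]
  covs <- lapply(split(as.data.frame(wide), grp), function(d)
    if (nrow(d) > 1) stats::cov(d) * (nrow(d) - 1) else NULL)
  covs <- covs[!vapply(covs, is.null, logical(1))]
  S <- Reduce(`+`, covs) / (nrow(wide) - length(covs))
  k <- ncol(S)
  dbar <- mean(diag(S)); mbar <- mean(S)
  num <- (k * (dbar - mbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Numeric vectors, n >= 3, finite, non-constant.
#' @return List (class `correlation_result`) with `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson_r: need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("pearson_r: zero variance in x or y", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  structure(list(r = unname(ct$estimate), n = length(x),
                 p = unname(ct$p.value)),
            class = "correlation_result")
}

#' Correlation panel: one response against many markers
#'
#' Pairwise-complete Pearson correlations of a response (e.g. day-2 maze
#' errors) with a list of marker columns, reported with unadjusted p values
#' (per-marker significance, the convention of the source analyses);
#' `adjust = "BH"` optionally appends Benjamini-Hochberg adjusted values.
#'
#' @param table data.frame holding the response and marker columns.
#' @param response Response column name.
#' @param markers Character vector of marker column names.
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return data.frame with `marker`, `r`, `n`, `p`, `error` (and `p_adj`
#'   when adjusted). An absent marker raises an error naming it; a
#'   degenerate marker (constant, too few pairs) is reported with `NA`
#'   values and its error message, leaving the other markers unaffected.
#' @export
correlation_panel <- function(table, response, markers, adjust = "none") {
  if (!response %in% names(table))
    stop("correlation_panel: response '", response, "' absent", call. = FALSE)
  miss <- setdiff(markers, names(table))
  if (length(miss))
    stop("correlation_panel: marker(s) absent: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(markers, function(m) {
    res <- tryCatch(pearson_r(table[[response]], table[[m]]),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(marker = m, r = NA_real_, n = NA_integer_, p = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(marker = m, r = res$r, n = res$n, p = res$p,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}

#' Average water-maze trials into blocks of three
#'
#' Consecutive non-overlapping triples of trial scores are averaged, order
#' preserved (six learning trials per day give two blocks; each memory test
#' is one block).
#'
#' @param trials Numeric vector of per-trial values (length divisible by 3),
#'   or a matrix with one row per subject.
#' @return Numeric vector of block means (or a matrix, subjects in rows).
#' @export
rawm_blocks <- function(trials) {
  if (is.matrix(trials))
    return(t(apply(trials, 1, rawm_blocks)))
  if (length(trials) %% 3 != 0)
    stop("rawm_blocks: trial count (", length(trials),
         ") not divisible by 3", call. = FALSE)
  as.numeric(colMeans(matrix(trials, nrow = 3)))
}

#' Delayed-matching-to-place improvement
#'
#' Per-day escape latency is the mean over that day's trials; improvement is
#' the day-`day_start` mean minus the day-`day_end` mean (positive = faster
#' escape at the end of testing).
#'
#' @param latencies data.frame with columns `subject`, `day`, `latency_s`
#'   (one row per trial).
#' @param day_start,day_end Days subtracted (defaults 20 and 23).
#' @return data.frame with `subject`, `improvement_s`, and the two per-day
#'   means.
#' @export
dmp_improvement <- function(latencies, day_start = 20, day_end = 23) {
  need <- c("subject", "day", "latency_s")
  miss <- setdiff(need, names(latencies))
  if (length(miss))
    stop("dmp_improvement: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- lapply(split(latencies, latencies$subject), function(d) {
    for (day in c(day_start, day_end))
      if (!any(d$day == day))
        stop("dmp_improvement: subject ", d$subject[1], " missing day ", day,
             call. = FALSE)
    m0 <- mean(d$latency_s[d$day == day_start])
    m1 <- mean(d$latency_s[d$day == day_end])
    data.frame(subject = d$subject[1], day_start_mean_s = m0,
               day_end_mean_s = m1, improvement_s = m0 - m1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference` (reference gene, e.g.
#' GAPDH); `ddCt = dCt - mean dCt of the calibrator group`; fold change is
#' `2^-ddCt`. The calibrator group's geometric-mean fold change is 1 by
#' construction.
#'
#' @param ct_target,ct_reference Paired per-sample Ct values.
#' @param group Per-sample group labels.
#' @param calibrator Calibrator group label.
#' @return data.frame with `group`, `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(ct_target, ct_reference, group, calibrator) {
  if (length(ct_target) != length(ct_reference) ||
      length(ct_target) != length(group))
    stop("ddct_fold_change: inputs must be the same length", call. = FALSE)
  if (anyNA(ct_reference))
    stop("ddct_fold_change: missing reference Ct for sample(s) ",
         paste(which(is.na(ct_reference)), collapse = ", "), call. = FALSE)
  if (!calibrator %in% group)
    stop("ddct_fold_change: calibrator group '", calibrator,
         "' not present", call. = FALSE)
  dct <- ct_target - ct_reference
  ddct <- dct - mean(dct[group == calibrator])
  data.frame(group = group, dct = dct, ddct = ddct,
             fold_change = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Densitometry fold change normalised to a loading control
#'
#' Band intensity is divided by the loading-control (actin) intensity, then
#' expressed relative to the mean ratio of the reference (vehicle) group,
#' whose mean fold change is exactly 1.
#'
#' @param band,actin Paired positive intensities.
#' @param group Per-sample group labels.
#' @param reference Reference group label.
#' @return data.frame with `group`, `ratio`, `fold_change`.
#' @export
densitometry_fold_change <- function(band, actin, group, reference) {
  if (any(band <= 0) || any(actin <= 0))
    stop("densitometry_fold_change: intensities must be positive", call. = FALSE)
  if (!reference %in% group)
    stop("densitometry_fold_change: reference group '", reference,
         "' not present", call. = FALSE)
  ratio <- band / actin
  data.frame(group = group, ratio = ratio,
             fold_change = ratio / mean(ratio[group == reference]),
             stringsAsFactors = FALSE)
}
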