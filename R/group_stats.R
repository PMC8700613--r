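#' Two-sample t-test (pooled variance, two-tailed)
#'
#' Student's t-test with pooled variance, the convention used for the
#' demographics and region-level comparisons here (a Welch variant is
#' available via `var_equal = FALSE`).
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @param var_equal pool the variances (default `TRUE`).
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite values in input")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    tstat <- if (d == 0) 0 else sign(d) * Inf
  } else tstat <- d / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Two-sample t-test from summary statistics
#'
#' Same pooled-variance test as [two_sample_ttest], computed from printed
#' sufficient statistics (mean, sd, n per group), e.g. to check a
#' demographics table against its reported p-values.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries; `n >= 2`,
#'   `sd >= 0`.
#' @return list with `t`, `df`, `p`.
#' @examples
#' ttest_from_summary(2.88, 1.94, 43, 2.00, 1.48, 43)$p  # ~0.020
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2")
  if (sd_a < 0 || sd_b < 0) stop("sd must be >= 0")
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  df <- n_a + n_b - 2
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  d <- mean_a - mean_b
  if (se == 0) {
    tstat <- if (d == 0) 0 else sign(d) * Inf
  } else tstat <- d / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square with 1
#' degree of freedom, e.g. for a sex-by-group table.
#'
#' @param a,b,c,d cell counts, row-wise: group1 (a, b), group2 (c, d).
#' @return list with `chi2`, `df = 1`, `p`.
#' @examples
#' chi_square_2x2(17, 26, 14, 29)$p  # ~0.5005
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  O <- matrix(cells, 2L, 2L, byrow = TRUE)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("all table margins must be positive")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1); significance is
#' declared on adjusted p < `q`.
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @param q FDR level (default 0.01).
#' @return list: `p_adjusted` (same order as input), `significant`
#'   (logical), `q`.
#' @export
fdr_bh <- function(p, q = 0.01) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  list(p_adjusted = adj, significant = adj < q, q = q)
}

#' Region-level two-group comparison with FDR control
#'
#' Runs a pooled-variance two-sample t-test on each region's mean AAPE and
#' adjusts across regions with Benjamini-Hochberg. Regions missing (NA
#' mean) in any subject are excluded from the family before adjustment and
#' listed in the `excluded_rois` attribute, so the multiplicity count is
#' explicit.
#'
#' @param profiles long data.frame (`subject_id`, `roi_id`, `mean_aape`,
#'   optionally `roi_name`) covering both groups.
#' @param groups named character/factor vector: subject_id -> group label;
#'   must contain exactly two levels.
#' @param q FDR level (default 0.01, i.e. "p < 0.01, FDR corrected").
#' @return data.frame, one row per tested region: `roi_id`, `roi_name`,
#'   `mean_<group1>`, `mean_<group2>`, `t`, `p`, `p_adjusted`,
#'   `significant`, `direction` (which group is lower). Attribute
#'   `excluded_rois` lists regions dropped for missingness.
#' @export
roi_group_analysis <- function(profiles, groups, q = 0.01) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) != 2L) stop("need exactly two groups, got: ",
                              paste(lev, collapse = ", "))
  if (is.null(names(groups))) stop("groups must be named by subject_id")
  profiles$group <- groups[as.character(profiles$subject_id)]
  if (any(is.na(profiles$group)))
    stop("subjects without a group label: ",
         paste(unique(profiles$subject_id[is.na(profiles$group)]),
               collapse = ", "))
  rois <- sort(unique(profiles$roi_id))
  bad <- vapply(rois, function(r) {
    sub <- profiles[profiles$roi_id == r, ]
    any(!is.finite(sub$mean_aape)) ||
      any(table(sub$group) < 2L) || length(unique(sub$group)) < 2L
  }, logical(1L))
  excluded <- rois[bad]
  if (length(excluded))
    message("regions excluded from the family (missing values): ",
            paste(excluded, collapse = ", "))
  rois <- rois[!bad]
  if (!length(rois)) stop("no testable regions remain")
  rows <- lapply(rois, function(r) {
    sub <- profiles[profiles$roi_id == r, ]
    a <- sub$mean_aape[sub$group == lev[1L]]
    b <- sub$mean_aape[sub$group == lev[2L]]
    tt <- two_sample_ttest(a, b)
    data.frame(roi_id = r,
               roi_name = if ("roi_name" %in% names(sub))
                 sub$roi_name[1L] else sprintf("ROI%03d", r),
               mean_a = mean(a), mean_b = mean(b),
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lev[1L])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lev[2L])
  adj <- fdr_bh(out$p, q)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$significant
  out$direction <- ifelse(out$t > 0, paste(lev[2L], "lower"),
                          ifelse(out$t < 0, paste(lev[1L], "lower"), "equal"))
  attr(out, "excluded_rois") <- excluded
  attr(out, "q") <- q
  out
}

#' Demographics comparison table
#'
#' Group-wise mean +/- sd and two-tailed p-value for each continuous
#' variable (pooled t-test) plus a chi-square test for the binary `sex`
#' column, in the style of a cohort demographics table.
#'
#' @param cohort data.frame with a `group` column (two levels), a binary
#'   `sex` column (0/1), and numeric columns to compare.
#' @param variables continuous columns to test (default: all numeric
#'   columns except `sex`).
#' @return data.frame: `variable`, `summary_<g1>`, `summary_<g2>`, `test`,
#'   `p`.
#' @export
demographics_table <- function(cohort, variables = NULL) {
  g <- droplevels(as.factor(cohort$group))
  lev <- levels(g)
  if (length(lev) != 2L) stop("cohort$group must have two levels")
  if (is.null(variables)) {
    num <- vapply(cohort, is.numeric, logical(1L))
    variables <- setdiff(names(cohort)[num], c("sex"))
  }
  fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
  rows <- lapply(variables, function(v) {
    a <- cohort[[v]][g == lev[1L]]; b <- cohort[[v]][g == lev[2L]]
    data.frame(variable = v, s1 = fmt(a), s2 = fmt(b), test = "t",
               p = two_sample_ttest(a, b)$p)
  })
  out <- do.call(rbind, rows)
  if ("sex" %in% names(cohort)) {
    tab <- table(factor(cohort$sex, levels = 0:1), g)
    cs <- chi_square_2x2(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
    out <- rbind(data.frame(
      variable = "sex",
      s1 = sprintf("%d/%d", tab[1, 1], tab[2, 1]),
      s2 = sprintf("%d/%d", tab[1, 2], tab[2, 2]),
      test = "chi2", p = cs$p), out)
  }
  names(out)[2:3] <- paste0("summary_", lev)
  rownames(out) <- NULL
  out
}
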