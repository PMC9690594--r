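# Group-level inference: unpaired t-test on TGS, one-way ANOVA with a
# linear-trend contrast over the ordered groups (control < national <
# international), TGS-performance regression, and performance-by-genotype
# contrasts. Wilks points are consumed as given (no body-weight adjustment).

.comparison <- function(groups, n, mean, sd, statistic, value, df, p,
                        effect = NULL) {
  structure(list(groups = groups, n = n, mean = mean, sd = sd,
                 statistic = statistic, value = value, df = df, p = p,
                 effect = effect),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$statistic, " = ", format(round(x$value, 3), nsmall = 3),
      ", df = ", paste(round(x$df, 1), collapse = ", "),
      ", p = ", format(round(x$p, 3), nsmall = 3), "\n", sep = "")
  for (i in seq_along(x$groups))
    cat("  ", x$groups[i], ": n = ", x$n[i], ", ",
        format(round(x$mean[i], 2), nsmall = 2), " ± ",
        format(round(x$sd[i], 2), nsmall = 2), "\n", sep = "")
  invisible(x)
}

#' Unpaired two-group t-test
#'
#' Equal-variance (pooled) t-test by default, as used for the published
#' TGS group comparisons; Welch's correction behind `welch = TRUE`.
#' Degenerate input (both groups constant and equal) returns t = 0, p = 1
#' with a `degenerate` flag.
#'
#' @param a,b Numeric vectors, each of length >= 2 (`NA` dropped).
#' @param labels Group labels, order preserved in output.
#' @param welch Use Welch's unequal-variance test.
#' @return A `group_comparison` (statistic `"t"`; `effect` = mean
#'   difference a - b with 95% CI).
#' @export
two_group_t <- function(a, b, labels = c("a", "b"), welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    out <- .comparison(labels, c(length(a), length(b)),
                       c(mean(a), mean(b)), c(0, 0), "t", 0,
                       length(a) + length(b) - 2L, 1,
                       effect = c(diff = 0, lo = 0, hi = 0))
    out$degenerate <- TRUE
    return(out)
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  .comparison(labels, c(length(a), length(b)), c(mean(a), mean(b)),
              c(stats::sd(a), stats::sd(b)), "t", unname(ht$statistic),
              unname(ht$parameter), ht$p.value,
              effect = c(diff = mean(a) - mean(b),
                         lo = ht$conf.int[1], hi = ht$conf.int[2]))
}

#' One-way ANOVA with a linear-trend contrast over ordered groups
#'
#' Omnibus F across the groups plus a linear-trend test over the group
#' ordering, fitted by least squares on equally spaced centered group
#' scores (for 3 groups: -1, 0, +1). For equal group sizes the trend t and
#' p coincide exactly with regressing the values on the group index; the
#' reported effect is the contrast estimate sum(w * group means).
#'
#' @param values Numeric vector.
#' @param group Factor-like vector; the level order defines the trend
#'   direction (e.g. control < national < international).
#' @return List of two `group_comparison`s: `omnibus` (statistic `"F"`) and
#'   `trend` (statistic `"trend-t"`, `effect` = contrast estimate).
#' @export
anova_with_trend <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- if (is.factor(group)) droplevels(group[keep]) else
    factor(group[keep], levels = unique(group[keep]))
  k <- nlevels(group)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  n <- tabulate(group)
  if (any(n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  m <- tapply(values, group, mean)
  s <- tapply(values, group, stats::sd)
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  omnibus <- .comparison(levels(group), n, as.numeric(m), as.numeric(s),
                         "F", an$`F value`[1], an$Df, an$`Pr(>F)`[1])
  # linear trend: least squares on centered equally spaced group scores
  w <- seq_len(k) - (k + 1) / 2
  score <- w[as.integer(group)]
  tfit <- summary(stats::lm(values ~ score))
  trend <- .comparison(levels(group), n, as.numeric(m), as.numeric(s),
                       "trend-t", tfit$coefficients[2, "t value"],
                       length(values) - 2L,
                       tfit$coefficients[2, "Pr(>|t|)"],
                       effect = c(contrast = sum(w * m)))
  list(omnibus = omnibus, trend = trend)
}

#' Regress performance on TGS
#'
#' Ordinary least squares of Wilks-point performance on the individual TGS,
#' estimating how much performance variance the score explains.
#'
#' @param cohort A `wl_cohort` with a `wilks` column.
#' @param model A `tgs_model`.
#' @param panel Locus panel.
#' @return A `group_comparison` (statistic `"slope-t"`) with `effect`
#'   carrying `slope`, `intercept`, `r_squared`; plus the `n` used.
#' @export
regress_performance_on_tgs <- function(cohort, model, panel = wl_panel()) {
  score <- tgs(model, cohort, panel)
  keep <- !is.na(score) & !is.na(cohort$wilks)
  x <- score[keep]; y <- cohort$wilks[keep]
  if (length(x) < 3L) stop("need >= 3 individuals with TGS and performance",
                           call. = FALSE)
  if (stats::sd(x) == 0) stop("zero TGS variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  .comparison("all", length(x), mean(y), stats::sd(y), "slope-t",
              sm$coefficients[2, "t value"], fit$df.residual,
              sm$coefficients[2, "Pr(>|t|)"],
              effect = c(slope = unname(stats::coef(fit)[2]),
                         intercept = unname(stats::coef(fit)[1]),
                         r_squared = sm$r.squared))
}

#' Compare performance between genotype groups at one locus
#'
#' Collapses the cohort's genotypes at a locus under a genetic grouping and
#' compares Wilks-point performance across the resulting groups: a t-test
#' for two groups (equivalently 2-group ANOVA), one-way ANOVA for three.
#' Groupings follow the locus's published dominant/recessive orientation;
#' empty genotype groups are reported and the comparison skipped.
#'
#' @param cohort A `wl_cohort` with a `wilks` column.
#' @param locus Gene symbol or rs id.
#' @param grouping `"dominant"`, `"recessive"` or `"genotypic"`.
#' @param panel Locus panel.
#' @return A `group_comparison`, or `NULL` (with a message) when a genotype
#'   group has fewer than 2 individuals.
#' @export
genotype_performance_compare <- function(cohort, locus,
                                         grouping = c("recessive", "dominant",
                                                      "genotypic"),
                                         panel = wl_panel()) {
  grouping <- match.arg(grouping)
  loc <- locus_info(locus, panel)
  g <- cohort[[loc$rs_id]]
  keep <- !is.na(g) & !is.na(cohort$wilks)
  g <- g[keep]; y <- cohort$wilks[keep]
  lab <- c(loc$gt_hi, loc$gt_het, loc$gt_lo)
  grp <- if (grouping == "genotypic") factor(g, levels = lab) else {
    split_hi <- (grouping == "dominant") == (loc$dominant_split == "hi")
    if (split_hi)  # hi-homozygote vs carrier of lo allele
      factor(ifelse(g == lab[1], lab[1],
                    paste(lab[2], lab[3], sep = "+")),
             levels = c(lab[1], paste(lab[2], lab[3], sep = "+")))
    else           # hi-allele carriers vs lo-homozygote
      factor(ifelse(g == lab[3], lab[3],
                    paste(lab[1], lab[2], sep = "+")),
             levels = c(paste(lab[1], lab[2], sep = "+"), lab[3]))
  }
  n <- table(grp)
  if (any(n < 2L)) {
    message("skipping ", loc$gene, " (", grouping, "): group(s) ",
            paste(names(n)[n < 2L], collapse = ", "), " have n < 2")
    return(NULL)
  }
  if (nlevels(grp) == 2L)
    two_group_t(y[grp == levels(grp)[1]], y[grp == levels(grp)[2]],
                labels = levels(grp))
  else
    anova_with_trend(y, grp)$omnibus
}
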