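# Hardy-Weinberg testing and case-control association under collapsed
# genetic models. All chi-square tests are plain Pearson (no continuity
# correction), matching how the published per-locus p-values were obtained.

#' Collapse genotype counts under a genetic model
#'
#' Collapses a locus's three genotype counts into the categories of a
#' genetic model. The dominant/recessive orientation follows the published
#' per-locus convention stored in the panel (`dominant_split`): with the
#' default `"hi"` split, dominant compares the hi-homozygote against
#' lo-allele carriers and recessive compares hi-allele carriers against the
#' lo-homozygote; ACTN3 uses the mirrored assignment. The allele model
#' counts 2n alleles; the genotypic model keeps all three categories.
#'
#' @param counts A `wl_counts` table (any group).
#' @param locus Gene symbol or rs id, a row of `counts`.
#' @param model One of `"dominant"`, `"recessive"`, `"allele"`,
#'   `"genotypic"`.
#' @param panel Locus panel.
#' @return Named integer vector of length 2 (or 3 for genotypic).
#' @examples
#' collapse_counts(wl_counts("controls"), "ACE", "dominant")  # DD vs ID+II
#' @export
collapse_counts <- function(counts, locus, model, panel = wl_panel()) {
  loc <- locus_info(locus, panel)
  row <- counts[counts$rs_id == loc$rs_id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("locus ", locus, " not in count table", call. = FALSE)
  v <- c(row$n_hi, row$n_het, row$n_lo)
  model <- match.arg(model, c("dominant", "recessive", "allele", "genotypic"))
  lab <- c(loc$gt_hi, loc$gt_het, loc$gt_lo)
  hi_side <- function() stats::setNames(c(v[1], v[2] + v[3]),
    c(lab[1], paste(lab[2], lab[3], sep = "+")))
  lo_side <- function() stats::setNames(c(v[1] + v[2], v[3]),
    c(paste(lab[1], lab[2], sep = "+"), lab[3]))
  switch(model,
    dominant  = if (loc$dominant_split == "hi") hi_side() else lo_side(),
    recessive = if (loc$dominant_split == "hi") lo_side() else hi_side(),
    allele    = stats::setNames(c(2L * v[1] + v[2], v[2] + 2L * v[3]),
                                c(loc$allele_hi, loc$allele_lo)),
    genotypic = stats::setNames(v, lab))
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' @param case,control Non-negative integer vectors of equal length k >= 2
#'   (collapsed genotype or allele counts).
#' @return List with `chi2`, `df` (= k - 1), `p`, and the `table` tested.
#'   A column whose margin is zero is a degenerate table and raises an error.
#' @export
chi_square_2xk <- function(case, control) {
  stopifnot(length(case) == length(control), length(case) >= 2L,
            all(case >= 0), all(control >= 0))
  tab <- rbind(case = case, control = control)
  if (any(colSums(tab) == 0))
    stop("degenerate table: zero-margin column", call. = FALSE)
  if (any(rowSums(tab) == 0))
    stop("degenerate table: empty group", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, table = tab)
}

#' Odds ratio with 95% confidence interval for a 2 x 2 table
#'
#' OR = ad/bc with a Wald interval on the log scale. Tables containing a
#' zero cell get the Haldane-Anscombe 0.5 correction in every cell and are
#' flagged `corrected`.
#'
#' @param tab 2 x 2 matrix, rows = groups (case on top), columns = exposure.
#' @return List with `or`, `ci` (length-2 vector), `corrected` flag.
#' @export
odds_ratio <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  corrected <- any(tab == 0)
  x <- tab + if (corrected) 0.5 else 0
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  se <- sqrt(sum(1 / x))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(or = or, ci = ci, corrected = corrected)
}

#' Chi-square test for Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts with the p^2, 2pq, q^2 expectation at
#' the observed allele frequency; Pearson chi-square with 1 degree of
#' freedom (two genotype df minus one estimated allele frequency).
#'
#' @param counts A `wl_counts` table or an integer vector
#'   (n_hi, n_het, n_lo) for a single locus.
#' @param locus Locus (required when `counts` is a table).
#' @param alpha Deviation threshold for the `in_hwe` flag.
#' @param panel Locus panel.
#' @return List with `chi2`, `p`, `in_hwe`, `monomorphic`, `expected`.
#' @export
hwe_test <- function(counts, locus = NULL, alpha = 0.05, panel = wl_panel()) {
  v <- if (inherits(counts, "wl_counts")) {
    loc <- locus_info(locus, panel)
    row <- counts[counts$rs_id == loc$rs_id, ]
    c(row$n_hi, row$n_het, row$n_lo)
  } else as.numeric(counts)
  stopifnot(length(v) == 3L, all(v >= 0), sum(v) > 0)
  n <- sum(v)
  p <- (2 * v[1] + v[2]) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chi2 = 0, p = 1, in_hwe = TRUE, monomorphic = TRUE,
                expected = v))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((v - e)^2 / e)
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = pval, in_hwe = pval >= alpha, monomorphic = FALSE,
       expected = e)
}

#' Bonferroni adjustment with explicit test count
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param m Number of tests (>= `length(p)` in typical use; must be > 0).
#' @return `pmin(1, p * m)`, order-preserving.
#' @export
bonferroni <- function(p, m) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  if (m <= 0) stop("m must be positive", call. = FALSE)
  pmin(1, p * m)
}

#' Case-control association screen over a locus panel
#'
#' Runs the collapsed-model chi-square comparison for every locus, model and
#' case group against the control table, reproducing the published p-value
#' grid from the packaged counts. Odds ratios are attached for 2 x 2 models.
#'
#' @param case_tables Named list of `wl_counts` case tables (e.g.
#'   weightlifters, international).
#' @param control_table `wl_counts` control table.
#' @param models Character vector of genetic models to screen.
#' @param panel Locus panel (screen runs over loci present in all tables).
#' @return A data.frame with one row per locus x model x case group:
#'   `gene`, `rs_id`, `case_group`, `model`, `chi2`, `df`, `p`, `or`,
#'   `or_lo`, `or_hi`.
#' @examples
#' tabs <- wl_counts()
#' scr <- case_control_screen(tabs[c("weightlifters", "international")],
#'                            tabs$controls)
#' subset(scr, p < 0.05)
#' @export
case_control_screen <- function(case_tables, control_table,
                                models = c("dominant", "recessive", "allele"),
                                panel = wl_panel()) {
  if (inherits(case_tables, "wl_counts"))
    case_tables <- stats::setNames(list(case_tables),
                                   attr(case_tables, "group"))
  loci <- Reduce(intersect, c(list(control_table$rs_id),
                              lapply(case_tables, `[[`, "rs_id")))
  rows <- list()
  for (g in names(case_tables)) {
    for (rs in loci) {
      for (m in models) {
        ca <- collapse_counts(case_tables[[g]], rs, m, panel)
        co <- collapse_counts(control_table, rs, m, panel)
        ht <- chi_square_2xk(ca, co)
        or <- if (length(ca) == 2L) odds_ratio(ht$table) else
          list(or = NA_real_, ci = c(NA_real_, NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = locus_info(rs, panel)$gene, rs_id = rs, case_group = g,
          model = m, chi2 = ht$chi2, df = ht$df, p = ht$p,
          or = or$or, or_lo = or$ci[1], or_hi = or$ci[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hardy-Weinberg screen over a locus panel
#'
#' @param tables A `wl_counts` table or named list of them.
#' @inheritParams hwe_test
#' @return Data.frame with `group`, `gene`, `rs_id`, `chi2`, `p`, `in_hwe`.
#' @export
hwe_screen <- function(tables, alpha = 0.05, panel = wl_panel()) {
  if (inherits(tables, "wl_counts"))
    tables <- stats::setNames(list(tables), attr(tables, "group"))
  rows <- list()
  for (g in names(tables)) {
    tab <- tables[[g]]
    for (rs in tab$rs_id) {
      h <- hwe_test(tab, rs, alpha, panel)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, gene = locus_info(rs, panel)$gene, rs_id = rs,
        chi2 = h$chi2, p = h$p, in_hwe = h$in_hwe,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
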