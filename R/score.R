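# Total genotype score (TGS) machinery: published score tables, the TGS
# formula, the data-driven weightlifting-related model (WRM) builder, and
# exact score distributions from marginal genotype counts.
#
# A score table assigns each locus's genotypes scores from {0, 1, 2}: the
# "optimal" homozygote scores 2, the heterozygote always 1, the other
# homozygote 0. The TGS of an individual is 100/(2L) times the summed score
# over the table's L loci, so it lives on a 0-100 scale.

.tgs_table1 <- function() {
  # optimal (score-2) genotype per locus, canonical labels:
  # PWM directions from the strength/power literature; WRM directions from
  # the case-control screen (6 loci; ACE and CHRNB3 flip direction vs PWM).
  data.frame(
    gene = c("ACE", "ACTN3", "ALDH2", "CHRNB3", "CKM", "CNTFR",
             "FTO", "GALNTL6", "IGF2", "MCT1", "PPARGC1A", "TRHR"),
    pwm  = c("II", "CC", "GG", "AA", "GG", "TT",
             "AA", "TT", "CC", "TT", "AA", "TT"),
    wrm  = c("DD", "CC", NA, "GG", NA, "TT",
             NA, NA, NA, "TT", "AA", NA),
    stringsAsFactors = FALSE)
}

#' Construct a TGS score table
#'
#' @param optimal Named character vector mapping gene symbol or rs id to the
#'   score-2 (optimal) genotype, canonical label or synonym. The heterozygote
#'   scores 1 and the opposite homozygote 0.
#' @param model_name Label for the model.
#' @param panel Locus panel.
#' @return A `tgs_model` data.frame with columns `gene`, `rs_id`, `s_hi`,
#'   `s_het`, `s_lo` and attributes `model_name` and `scale` = 100/(2L).
#' @export
score_table <- function(optimal, model_name = "user", panel = wl_panel()) {
  rows <- lapply(names(optimal), function(nm) {
    loc <- locus_info(nm, panel)
    opt <- canonical_genotype(optimal[[nm]], nm, panel)
    if (is.na(opt) || opt == loc$gt_het)
      stop("optimal genotype for ", nm, " must be a homozygote",
           call. = FALSE)
    data.frame(gene = loc$gene, rs_id = loc$rs_id,
               s_hi = if (opt == loc$gt_hi) 2L else 0L,
               s_het = 1L,
               s_lo = if (opt == loc$gt_lo) 2L else 0L,
               stringsAsFactors = FALSE)
  })
  x <- do.call(rbind, rows)
  structure(x, model_name = model_name, scale = 100 / (2 * nrow(x)),
            class = c("tgs_model", "data.frame"))
}

#' @export
print.tgs_model <- function(x, ...) {
  cat("TGS score table '", attr(x, "model_name"), "': ", nrow(x),
      " loci, scale 100/", 2 * nrow(x), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Published score tables: PWM and WRM
#'
#' `pwm_model()` is the 12-locus power-oriented whole model with score
#' directions taken from the prior strength/power literature;
#' `wrm_model()` is the 6-locus weightlifting-related model whose loci and
#' directions came from the case-control screen (see [build_wrm()], which
#' re-derives it from the counts).
#'
#' @return A `tgs_model`; PWM scale 100/24, WRM scale 100/12.
#' @examples
#' wrm_model()
#' @export
pwm_model <- function() {
  t1 <- .tgs_table1()
  score_table(stats::setNames(t1$pwm, t1$gene), "PWM")
}

#' @rdname pwm_model
#' @export
wrm_model <- function() {
  t1 <- .tgs_table1()
  keep <- !is.na(t1$wrm)
  score_table(stats::setNames(t1$wrm[keep], t1$gene[keep]), "WRM")
}

.score_lookup <- function(model, rs, genotype, panel) {
  loc <- locus_info(rs, panel)
  row <- model[model$rs_id == loc$rs_id, ]
  s <- c(row$s_hi, row$s_het, row$s_lo)
  s[match(genotype, c(loc$gt_hi, loc$gt_het, loc$gt_lo))]
}

#' TGS of individuals
#'
#' Computes the 0-100 total genotype score of each cohort row (or of a
#' single named genotype vector) under a score table. Individuals missing a
#' genotype at any table locus get `NA` (no proration); the number excluded
#' is reported via the `n_missing` attribute.
#'
#' @param model A `tgs_model`.
#' @param x A `wl_cohort` data.frame, or a named character vector mapping
#'   rs id (or gene) to genotype for one individual.
#' @param panel Locus panel.
#' @return Numeric vector of TGS values in \[0, 100\].
#' @examples
#' tgs(wrm_model(), c(ACE = "ID", ACTN3 = "RX", CHRNB3 = "AA",
#'                    CNTFR = "CT", MCT1 = "TA", PPARGC1A = "GA"))
#' @export
tgs <- function(model, x, panel = wl_panel()) {
  stopifnot(inherits(model, "tgs_model"))
  if (!is.data.frame(x)) {
    rs <- vapply(names(x), function(nm) locus_info(nm, panel)$rs_id, "")
    g <- stats::setNames(as.list(x), rs)
    missing <- setdiff(model$rs_id, rs)
    if (length(missing))
      stop("genotype vector lacks table loci: ",
           paste(missing, collapse = ", "), call. = FALSE)
    x <- as.data.frame(lapply(g, identity), stringsAsFactors = FALSE)
    names(x) <- rs
    for (r in rs) x[[r]] <- canonical_genotype(x[[r]], r, panel)
    single <- TRUE
  } else single <- FALSE
  missing <- setdiff(model$rs_id, names(x))
  if (length(missing))
    stop("cohort lacks table loci: ", paste(missing, collapse = ", "),
         call. = FALSE)
  total <- numeric(nrow(x))
  for (rs in model$rs_id)
    total <- total + .score_lookup(model, rs, x[[rs]], panel)
  out <- attr(model, "scale") * total
  if (single && anyNA(out))
    stop("missing genotype: TGS undefined for incomplete vectors",
         call. = FALSE)
  structure(out, n_missing = sum(is.na(out)))
}

#' Expected TGS from marginal genotype counts
#'
#' By linearity of expectation, the group-mean TGS depends only on the
#' per-locus genotype frequencies: mean = scale x sum over loci of
#' (score x count) / n. This is how the published group means are
#' reproduced from the count tables alone; no individual-level data and no
#' standard deviation are available on this route.
#'
#' @param model A `tgs_model`.
#' @param counts A `wl_counts` table covering every table locus.
#' @param panel Locus panel.
#' @return A `tgs_summary` list: `group`, `n`, `mean`, `sd` (`NA` here),
#'   `pmf` (`NULL` here), `scale`.
#' @examples
#' tgs_mean_from_counts(wrm_model(), wl_counts("controls"))$mean  # 32.93
#' @export
tgs_mean_from_counts <- function(model, counts, panel = wl_panel()) {
  miss <- setdiff(model$rs_id, counts$rs_id)
  if (length(miss))
    stop("count table lacks loci: ", paste(miss, collapse = ", "),
         call. = FALSE)
  total <- 0
  for (rs in model$rs_id) {
    row <- counts[counts$rs_id == rs, ]
    m <- model[model$rs_id == rs, ]
    n <- row$n_hi + row$n_het + row$n_lo
    total <- total + (m$s_hi * row$n_hi + m$s_het * row$n_het +
                      m$s_lo * row$n_lo) / n
  }
  structure(list(group = attr(counts, "group"), n = attr(counts, "n_total"),
                 mean = attr(model, "scale") * total, sd = NA_real_,
                 pmf = NULL, scale = attr(model, "scale")),
            class = "tgs_summary")
}

#' @export
print.tgs_summary <- function(x, ...) {
  cat("TGS summary: group '", x$group, "', n = ", x$n,
      ", mean = ", format(round(x$mean, 2), nsmall = 2),
      if (!is.na(x$sd)) paste0(", sd = ", format(round(x$sd, 2), nsmall = 2)),
      "\n", sep = "")
  invisible(x)
}

#' Exact TGS distribution under locus independence
#'
#' Treats each locus's genotype as an independent draw from its marginal
#' frequency in the count table and convolves the per-locus score
#' distributions into the exact probability mass function of the integer
#' score sum (0 .. 2L). The mean equals [tgs_mean_from_counts()] by
#' linearity; the spread and tail probabilities additionally assume
#' independence, which marginal counts cannot confirm.
#'
#' @inheritParams tgs_mean_from_counts
#' @return A `tgs_summary` with `pmf` (data.frame `sum`, `tgs`, `prob`),
#'   `mean`, and `sd` (of the scaled score).
#' @export
tgs_distribution <- function(model, counts, panel = wl_panel()) {
  miss <- setdiff(model$rs_id, counts$rs_id)
  if (length(miss))
    stop("count table lacks loci: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pmf <- 1  # distribution of the running sum, index = sum value + 1
  for (rs in model$rs_id) {
    row <- counts[counts$rs_id == rs, ]
    m <- model[model$rs_id == rs, ]
    n <- row$n_hi + row$n_het + row$n_lo
    p_locus <- numeric(3)  # P(score = 0, 1, 2)
    p_locus[m$s_hi + 1L] <- p_locus[m$s_hi + 1L] + row$n_hi / n
    p_locus[m$s_het + 1L] <- p_locus[m$s_het + 1L] + row$n_het / n
    p_locus[m$s_lo + 1L] <- p_locus[m$s_lo + 1L] + row$n_lo / n
    new <- numeric(length(pmf) + 2L)
    for (s in 0:2)
      new[seq_along(pmf) + s] <- new[seq_along(pmf) + s] + pmf * p_locus[s + 1L]
    pmf <- new
  }
  sums <- seq_along(pmf) - 1L
  scale <- attr(model, "scale")
  mu <- sum(sums * pmf)
  sdev <- sqrt(sum((sums - mu)^2 * pmf))
  structure(list(group = attr(counts, "group"), n = attr(counts, "n_total"),
                 mean = scale * mu, sd = scale * sdev,
                 pmf = data.frame(sum = sums, tgs = scale * sums, prob = pmf),
                 scale = scale),
            class = "tgs_summary")
}

#' Proportion of TGS values at or above a threshold
#'
#' On a `tgs_summary` with a pmf this is the exact tail probability under
#' locus independence; on a numeric vector of individual TGS values it is
#' the empirical fraction (missing values dropped).
#'
#' @param x A `tgs_summary` with `pmf`, or a numeric vector of TGS values.
#' @param threshold TGS threshold in \[0, 100\] (default 50).
#' @return Proportion in \[0, 1\].
#' @export
proportion_at_least <- function(x, threshold = 50) {
  if (threshold < 0 || threshold > 100)
    stop("threshold must be in [0, 100]", call. = FALSE)
  if (inherits(x, "tgs_summary")) {
    if (is.null(x$pmf)) stop("summary has no pmf", call. = FALSE)
    sum(x$pmf$prob[x$pmf$tgs >= threshold])
  } else {
    x <- x[!is.na(x)]
    mean(x >= threshold)
  }
}

#' Compare two groups' threshold proportions
#'
#' 2 x 2 Pearson chi-square on the counts above/below the TGS threshold.
#'
#' @param tgs_a,tgs_b Numeric vectors of individual TGS values.
#' @param threshold TGS threshold.
#' @return List with `prop_a`, `prop_b`, `chi2`, `p`.
#' @export
compare_threshold_proportions <- function(tgs_a, tgs_b, threshold = 50) {
  a <- tgs_a[!is.na(tgs_a)]; b <- tgs_b[!is.na(tgs_b)]
  tab <- rbind(c(sum(a >= threshold), sum(a < threshold)),
               c(sum(b >= threshold), sum(b < threshold)))
  ht <- chi_square_2xk(tab[1, ], tab[2, ])
  list(prop_a = mean(a >= threshold), prop_b = mean(b >= threshold),
       chi2 = ht$chi2, p = ht$p)
}

#' Build the weightlifting-related score model from a case-control screen
#'
#' Selects every locus for which any screened model reaches `p < alpha` in
#' either case group, and orients the scores so that the allele enriched in
#' the triggering case group relative to controls defines the score-2
#' homozygote (heterozygote = 1). When both case groups trigger a locus the
#' all-weightlifter comparison defines enrichment; otherwise the
#' significant group does. On the packaged counts this reproduces the
#' published 6-locus WRM, including the two direction flips relative to
#' the PWM (ACE and CHRNB3).
#'
#' @param screen Result of [case_control_screen()].
#' @param case_tables Named list of case `wl_counts` (same names as in the
#'   screen), used for allele frequencies.
#' @param control_table Control `wl_counts`.
#' @param alpha Selection threshold on the unadjusted p-value.
#' @param model_name Label for the resulting table.
#' @param panel Locus panel.
#' @return A `tgs_model` with a `selection` attribute (data.frame: per
#'   selected locus the triggering group, model and p-value).
#' @export
build_wrm <- function(screen, case_tables, control_table, alpha = 0.05,
                      model_name = "WRM", panel = wl_panel()) {
  hits <- screen[screen$p < alpha, , drop = FALSE]
  if (nrow(hits) == 0L)
    stop("empty model: no locus passes the screen at alpha = ", alpha,
         call. = FALSE)
  sel <- list(); optimal <- character()
  for (rs in unique(hits$rs_id)) {
    h <- hits[hits$rs_id == rs, ]
    # broader case group (earlier in case_tables) takes precedence when
    # both trigger; otherwise the single significant group defines direction
    cand <- names(case_tables)[names(case_tables) %in% h$case_group]
    grp <- if (length(cand)) cand[1] else h$case_group[which.min(h$p)]
    if (!grp %in% names(case_tables))
      stop("screen group '", grp, "' missing from case_tables", call. = FALSE)
    loc <- locus_info(rs, panel)
    freq_hi <- function(tab) {
      r <- tab[tab$rs_id == rs, ]
      (2 * r$n_hi + r$n_het) / (2 * (r$n_hi + r$n_het + r$n_lo))
    }
    f_case <- freq_hi(case_tables[[grp]])
    f_ctl <- freq_hi(control_table)
    if (f_case == f_ctl)
      stop("unresolved direction: allele-frequency tie at ", loc$gene,
           call. = FALSE)
    optimal[loc$gene] <- if (f_case > f_ctl) loc$gt_hi else loc$gt_lo
    hg <- h[h$case_group == grp, , drop = FALSE]
    top <- hg[which.min(hg$p), ]
    sel[[loc$gene]] <- data.frame(gene = loc$gene, rs_id = rs,
                                  triggered_by = grp, model = top$model,
                                  p = top$p, stringsAsFactors = FALSE)
  }
  out <- score_table(optimal, model_name, panel)
  attr(out, "selection") <- do.call(rbind, sel)
  out
}

#' Serialize / read a score table as JSON
#'
#' @param model A `tgs_model`.
#' @param path File path.
#' @param panel Locus panel.
#' @return `read_score_table()`: a `tgs_model`.
#' @export
write_score_table <- function(model, path, panel = wl_panel()) {
  i <- match(model$rs_id, panel$rs_id)
  entries <- lapply(seq_len(nrow(model)), function(k) {
    scores <- stats::setNames(
      c(model$s_hi[k], model$s_het[k], model$s_lo[k]),
      c(panel$gt_hi[i[k]], panel$gt_het[i[k]], panel$gt_lo[i[k]]))
    list(gene = model$gene[k], rs_id = model$rs_id[k],
         scores = as.list(scores))
  })
  jsonlite::write_json(
    list(model_name = attr(model, "model_name"),
         scale_denominator = 2L * nrow(model), entries = entries),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path, panel = wl_panel()) {
  x <- jsonlite::read_json(path)
  optimal <- character()
  for (e in x$entries) {
    scores <- unlist(e$scores)
    optimal[e$rs_id] <- names(scores)[scores == 2][1]
  }
  score_table(optimal, x$model_name, panel)
}
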