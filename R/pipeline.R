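# End-to-end orchestration of the two studies: the discovery study
# (HWE screen -> case-control screen -> WRM construction -> TGS summaries
# -> performance analyses) and the validation study (a fixed WRM applied to
# an independent case group, no re-fitting).

.fmt_p <- function(p) formatC(round(p, 3), format = "f", digits = 3)

#' Run the discovery study
#'
#' Executes the full discovery pipeline: Hardy-Weinberg screen, per-locus
#' case-control screen under the dominant/recessive/allele models,
#' data-driven WRM construction, PWM and WRM TGS summaries per ordered
#' group, TGS-threshold proportions, and - when an individual-level cohort
#' is supplied - the performance analyses (genotype contrasts and
#' TGS-performance regression). In fixture mode everything is recomputed
#' deterministically from the packaged published counts.
#'
#' @param input `"fixture"` (default) to use the packaged counts; a
#'   `wl_cohort` data.frame; or a [sim_config()] to simulate one.
#' @param alpha Significance threshold for screening and flags.
#' @param bonferroni_m Test counts for the reported adjusted p-values
#'   (both the per-model and the per-locus convention are listed).
#' @param out_dir Optional directory; when given, TSV/JSON reports are
#'   written (association table, WRM JSON, TGS summaries, run log).
#' @param threshold TGS threshold for the proportion comparison.
#' @param panel Locus panel.
#' @return A list: `hwe`, `screen` (with `p_bonferroni` columns), `wrm`,
#'   `tgs_summaries`, `threshold`, and in cohort mode `performance` and
#'   `regression`.
#' @examples
#' res <- run_study1()
#' res$tgs_summaries$WRM
#' @export
run_study1 <- function(input = "fixture", alpha = 0.05,
                       bonferroni_m = c(6, 12), out_dir = NULL,
                       threshold = 50, panel = wl_panel()) {
  cohort <- NULL
  if (inherits(input, "sim_config")) {
    cohort <- simulate_study(input, panel)
    input <- cohort
  }
  if (is.data.frame(input)) {
    cohort <- input
    groups <- intersect(c("control", "national", "international"),
                        unique(cohort$group))
    tabs <- stats::setNames(
      lapply(groups, counts_from_cohort, cohort = cohort, panel = panel),
      groups)
    # all-weightlifter table = national + international pooled
    wl <- cohort[cohort$group %in% c("national", "international"), ]
    wl$group <- "weightlifters"
    tabs$weightlifters <- counts_from_cohort(wl, "weightlifters", panel)
    control <- tabs$control
    national <- tabs$national
    international <- tabs$international
  } else if (identical(input, "fixture")) {
    f <- wl_counts()
    control <- f$controls
    international <- f$international
    national <- derive_national(f$weightlifters, f$international)
    tabs <- list(controls = control, weightlifters = f$weightlifters,
                 national = national, international = international)
  } else stop("input must be 'fixture', a cohort, or a sim_config",
              call. = FALSE)

  hwe <- hwe_screen(list(controls = control,
                         weightlifters = tabs$weightlifters,
                         international = international),
                    alpha, panel)
  screen <- case_control_screen(
    list(weightlifters = tabs$weightlifters,
         international = international),
    control, panel = panel)
  for (m in bonferroni_m)
    screen[[paste0("p_bonferroni_m", m)]] <- bonferroni(screen$p, m)
  wrm <- build_wrm(screen,
                   list(weightlifters = tabs$weightlifters,
                        international = international),
                   control, alpha, panel = panel)
  models <- list(PWM = pwm_model(), WRM = wrm)
  ordered <- list(control = control, national = national,
                  international = international)
  summaries <- lapply(models, function(mod)
    lapply(ordered, function(tab) tgs_distribution(mod, tab, panel)))
  thresh <- list(
    threshold = threshold,
    independence_pmf = lapply(summaries$WRM, proportion_at_least,
                              threshold = threshold))

  out <- list(hwe = hwe, screen = screen, wrm = wrm,
              tgs_summaries = summaries, threshold = thresh)

  if (!is.null(cohort)) {
    score <- list()
    for (nm in names(models)) score[[nm]] <- tgs(models[[nm]], cohort, panel)
    grp <- factor(cohort$group,
                  levels = intersect(c("control", "national",
                                       "international"),
                                     unique(cohort$group)))
    is_case <- cohort$group != "control"
    out$tgs_individual <- score
    out$t_test <- lapply(score, function(s)
      two_group_t(s[is_case], s[!is_case],
                  labels = c("weightlifters", "control")))
    out$anova <- lapply(score, function(s) anova_with_trend(s, grp))
    if ("wilks" %in% names(cohort) && any(!is.na(cohort$wilks))) {
      ath <- cohort[is_case, , drop = FALSE]
      out$performance <- lapply(stats::setNames(wrm$rs_id, wrm$gene),
                                function(rs)
        genotype_performance_compare(ath, rs, "dominant", panel))
      out$regression <- regress_performance_on_tgs(ath, wrm, panel)
    }
    out$threshold$empirical <- tapply(score$WRM >= threshold, cohort$group,
                                      function(z) mean(z, na.rm = TRUE))
  }

  if (!is.null(out_dir)) .write_reports(out, out_dir)
  out
}

#' Run the validation study
#'
#' Applies a fixed, previously built WRM to a second case group (e.g.
#' strength and power athletes): per-locus case-control screen and a TGS
#' comparison against controls. No model re-fitting takes place.
#'
#' @param case_table A `wl_counts` table for the validation case group, or
#'   a `wl_cohort` containing a control group and one case group.
#' @param wrm The fixed `tgs_model` from the discovery study.
#' @param control_table Control `wl_counts` (defaults to the packaged
#'   controls; ignored in cohort mode).
#' @param panel Locus panel.
#' @return A list: `screen`, `tgs_summaries` (mean via count linearity,
#'   control and case), and in cohort mode `t_test`.
#' @export
run_study2 <- function(case_table, wrm, control_table = NULL,
                       panel = wl_panel()) {
  stopifnot(inherits(wrm, "tgs_model"))
  if (is.data.frame(case_table) && inherits(case_table, "wl_cohort")) {
    cohort <- case_table
    miss <- setdiff(wrm$rs_id, names(cohort))
    if (length(miss))
      stop("panel mismatch: cohort lacks WRM loci ",
           paste(miss, collapse = ", "), call. = FALSE)
    case_groups <- setdiff(unique(cohort$group), "control")
    control_table <- counts_from_cohort(cohort, "control", panel)
    case_table <- counts_from_cohort(cohort, case_groups[1], panel)
    score <- tgs(wrm, cohort, panel)
    t_test <- two_group_t(score[cohort$group != "control"],
                          score[cohort$group == "control"],
                          labels = c(case_groups[1], "control"))
  } else {
    if (is.null(control_table)) control_table <- wl_counts("controls")
    t_test <- NULL
  }
  miss <- setdiff(wrm$rs_id, case_table$rs_id)
  if (length(miss))
    stop("panel mismatch: case table lacks WRM loci ",
         paste(miss, collapse = ", "), call. = FALSE)
  sub <- function(tab) {
    x <- tab[tab$rs_id %in% wrm$rs_id, , drop = FALSE]
    structure(x, group = attr(tab, "group"), n_total = attr(tab, "n_total"),
              class = class(tab))
  }
  screen <- case_control_screen(
    stats::setNames(list(sub(case_table)), attr(case_table, "group")),
    sub(control_table), panel = panel)
  list(screen = screen,
       tgs_summaries = list(
         control = tgs_mean_from_counts(wrm, control_table, panel),
         case = tgs_mean_from_counts(wrm, case_table, panel)),
       t_test = t_test)
}

# TSV/JSON report bundle; p-values at 3 decimals, TGS at 2, full precision
# in the JSON variants.
.write_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assoc <- res$screen
  assoc$p_printed <- .fmt_p(assoc$p)
  utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$hwe, file.path(out_dir, "hwe.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_score_table(res$wrm, file.path(out_dir, "wrm.json"))
  tg <- do.call(rbind, lapply(names(res$tgs_summaries), function(mod)
    do.call(rbind, lapply(res$tgs_summaries[[mod]], function(s)
      data.frame(model = mod, group = s$group, n = s$n,
                 mean = round(s$mean, 2), sd = round(s$sd, 2))))))
  utils::write.table(tg, file.path(out_dir, "tgs_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(wrm_selection = attr(res$wrm, "selection"),
         threshold = res$threshold,
         screen = res$screen),
    file.path(out_dir, "study1.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
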