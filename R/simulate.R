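# Synthetic cohort generator. Emulates the study's structure: per-locus
# multinomial genotype draws at the published group frequencies (or at HWE
# proportions from the allele frequency), ordered group structure
# (control < national < international), and a Gaussian Wilks-point
# performance model with additive per-locus genotype-group mean shifts.
# Loci are drawn independently (the analysis itself never models LD).

#' Default performance effect model
#'
#' Additive Gaussian model for Wilks-point performance, calibrated to the
#' published performance-by-genotype contrasts in weightlifters: ACTN3
#' XX-homozygotes shifted down by 8.77 points (193.32 vs 184.55) and CNTFR
#' CC-homozygotes down by 11.68 points (197.0 vs 185.32). The baseline
#' 199.65 solves the mixture equations at the all-weightlifter genotype
#' frequencies so that all four published group means are recovered in
#' expectation; residual sd 27 approximates the published group sds
#' (24-30).
#'
#' @param baseline Intercept (Wilks points).
#' @param sd Residual standard deviation (> 0).
#' @param shifts Named list: rs id -> named numeric vector of mean shifts
#'   keyed by canonical genotype label (absent genotypes shift 0).
#' @return An `effect_model` list.
#' @export
effect_model <- function(baseline = 199.65, sd = 27,
                         shifts = list(
                           rs1815739 = c(TT = -8.77),
                           rs41274853 = c(CC = -11.68))) {
  stopifnot(sd > 0)
  structure(list(baseline = baseline, sd = sd, shifts = shifts),
            class = "effect_model")
}

#' Simulation configuration
#'
#' @param n Named integer vector of group sizes; defaults to the study's
#'   416 controls, 125 national- and 67 international-level lifters.
#' @param source `"empirical"` draws genotypes at each group's packaged
#'   frequencies (requires `enrichment`); `"hwe"` draws at Hardy-Weinberg
#'   proportions computed from the group's allele frequency.
#' @param enrichment If `TRUE` (default) each group uses its own published
#'   frequencies, creating true TGS group differences; if `FALSE` all
#'   groups draw at control frequencies (the null).
#' @param effects An [effect_model()] (or `NULL` to skip performance).
#' @param seed Integer seed; required, every draw flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = c(control = 416, national = 125,
                             international = 67),
                       source = c("empirical", "hwe"),
                       enrichment = TRUE,
                       effects = effect_model(),
                       seed) {
  stopifnot(all(n > 0), !missing(seed))
  structure(list(n = n, source = match.arg(source),
                 enrichment = enrichment, effects = effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# genotype probabilities (hi, het, lo) for one group at one locus
.geno_probs <- function(tab, rs, source) {
  r <- tab[tab$rs_id == rs, ]
  n <- r$n_hi + r$n_het + r$n_lo
  if (source == "hwe") {
    p <- (2 * r$n_hi + r$n_het) / (2 * n)
    c(p^2, 2 * p * (1 - p), (1 - p)^2)
  } else c(r$n_hi, r$n_het, r$n_lo) / n
}

# fixture count table for a simulated group label
.group_source_table <- function(group, enrichment, tabs) {
  if (!enrichment) return(tabs$controls)
  switch(group,
         control = tabs$controls,
         national = derive_national(tabs$weightlifters, tabs$international),
         international = tabs$international,
         tabs$controls)  # study-2 style disciplines draw at control freqs
}

#' Simulate genotypes for a cohort
#'
#' Independent categorical draws per locus at the configured genotype
#' probabilities, group by group then locus by locus (so adding a locus to
#' the panel does not perturb earlier columns within a group).
#'
#' @param config A [sim_config()].
#' @param panel Locus panel to simulate.
#' @return A `wl_cohort` with columns `id`, `group` and one per rs id.
#' @export
simulate_genotypes <- function(config, panel = wl_panel()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tabs <- wl_counts()
  groups <- names(config$n)
  out <- list()
  for (g in groups) {
    src <- .group_source_table(g, config$enrichment, tabs)
    ng <- config$n[[g]]
    block <- data.frame(id = sprintf("%s_%04d", g, seq_len(ng)),
                        group = g, stringsAsFactors = FALSE)
    for (rs in panel$rs_id) {
      loc <- locus_info(rs, panel)
      pr <- .geno_probs(src, rs, config$source)
      if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
        stop("invalid genotype probabilities at ", rs, call. = FALSE)
      block[[rs]] <- sample(c(loc$gt_hi, loc$gt_het, loc$gt_lo), ng,
                            replace = TRUE, prob = pr)
    }
    out[[g]] <- block
  }
  x <- do.call(rbind, out)
  rownames(x) <- NULL
  class(x) <- c("wl_cohort", "data.frame")
  x
}

#' Add simulated performance to a cohort
#'
#' performance = baseline + sum of genotype-group mean shifts + Gaussian
#' noise. Deterministic given the seed; with `sd` effectively zero the
#' genotype groups determine performance exactly.
#'
#' @param cohort A `wl_cohort` genotyped at every effect locus.
#' @param effects An [effect_model()].
#' @param seed Integer seed for the noise draws.
#' @param groups Group labels that receive a performance value (default:
#'   all non-control groups, mirroring that only athletes have Wilks
#'   points).
#' @return The cohort with a `wilks` column (`NA` outside `groups`).
#' @export
simulate_performance <- function(cohort, effects = effect_model(), seed,
                                 groups = setdiff(unique(cohort$group),
                                                  "control")) {
  stopifnot(inherits(effects, "effect_model"), !missing(seed))
  miss <- setdiff(names(effects$shifts), names(cohort))
  if (length(miss))
    stop("effect locus absent from cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  mu <- rep(effects$baseline, nrow(cohort))
  for (rs in names(effects$shifts)) {
    sh <- effects$shifts[[rs]]
    hit <- match(cohort[[rs]], names(sh))
    mu <- mu + ifelse(is.na(hit), 0, sh[hit])
  }
  w <- stats::rnorm(nrow(cohort), mu, effects$sd)
  w[!cohort$group %in% groups] <- NA_real_
  cohort$wilks <- w
  cohort
}

#' Simulate a full study dataset
#'
#' Orchestrates [simulate_genotypes()] and [simulate_performance()] into
#' one cohort containing every configured group. With `enrichment = TRUE`
#' case groups draw at their published genotype frequencies, creating the
#' ordered TGS structure (control < national < international); with
#' `enrichment = FALSE` all groups draw at control frequencies, giving a
#' null dataset for calibration.
#'
#' @param config A [sim_config()].
#' @param panel Locus panel.
#' @return A `wl_cohort` with genotypes and (unless `config$effects` is
#'   `NULL`) a `wilks` column for the athlete groups.
#' @export
simulate_study <- function(config, panel = wl_panel()) {
  cohort <- simulate_genotypes(config, panel)
  if (!is.null(config$effects))
    cohort <- simulate_performance(cohort, config$effects,
                                   seed = config$seed + 1L)
  cohort
}
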