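# Synthetic cohort generator: reproducibility, frequency convergence,
# HWE calibration, effect-model recovery, pipeline round trip.

test_that("simulation is fully reproducible under a fixed seed", {
  cfg <- sim_config(n = c(control = 50, national = 30), seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  # byte-identical TSV output
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(a, p1); write_cohort(b, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the draw
  expect_false(identical(
    a, simulate_study(sim_config(n = cfg$n, seed = 100))))
})

test_that("genotype marginals converge to the configured frequencies", {
  cfg <- sim_config(n = c(control = 100000), seed = 7, effects = NULL)
  co <- simulate_genotypes(cfg)
  f <- fixture_tables()
  cc <- counts_from_cohort(co, "control")
  for (rs in wl_panel()$rs_id) {
    got <- cc[cc$rs_id == rs, c("n_hi", "n_het", "n_lo")] / 1e5
    want <- f$controls[f$controls$rs_id == rs,
                       c("n_hi", "n_het", "n_lo")] / 416
    expect_true(all(abs(got - want) < 0.005))
  }
})

test_that("a group-sized draw stays within multinomial sampling error", {
  cfg <- sim_config(n = c(control = 416), seed = 13, effects = NULL)
  cc <- counts_from_cohort(simulate_genotypes(cfg), "control")
  f <- fixture_tables()
  for (rs in wl_panel()$rs_id) {
    got <- unlist(cc[cc$rs_id == rs, c("n_hi", "n_het", "n_lo")])
    want <- unlist(f$controls[f$controls$rs_id == rs,
                              c("n_hi", "n_het", "n_lo")])
    p <- want / 416
    # 4 sd of Binomial(416, p) per cell
    expect_true(all(abs(got - want) <= 4 * sqrt(416 * p * (1 - p)) + 1))
  }
})

test_that("HWE-mode draws pass the HWE test at its nominal rate", {
  set.seed(17)
  seeds <- sample.int(1e6, 1000)
  pass <- vapply(seeds, function(s) {
    cfg <- sim_config(n = c(control = 416), seed = s, source = "hwe",
                      effects = NULL)
    co <- simulate_genotypes(cfg, panel = wl_panel()[6, ])  # CNTFR only
    cc <- counts_from_cohort(co, "control")
    hwe_test(unlist(cc[1, c("n_hi", "n_het", "n_lo")]))$in_hwe
  }, NA)
  expect_gte(mean(pass), 0.93)
})

test_that("performance model recovers the published genotype contrasts", {
  # across seeds, the ACTN3 and CNTFR group means sit at the published
  # values (193.32 / 184.55 and 185.32 / 197.0)
  set.seed(19)
  n_seeds <- 200
  m <- matrix(NA_real_, n_seeds, 4)
  cfg0 <- sim_config(n = c(national = 125, international = 67), seed = 1)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(n = cfg0$n, seed = 1000L + i)
    co <- simulate_study(cfg)
    rr <- co$rs1815739 != "TT"
    cc <- co$rs41274853 == "CC"
    m[i, ] <- c(mean(co$wilks[rr]), mean(co$wilks[!rr]),
                mean(co$wilks[cc]), mean(co$wilks[!cc]))
  }
  got <- colMeans(m)
  expect_equal(got[1], 193.32, tolerance = 1 / 193)   # within 1 Wilks point
  expect_equal(got[2], 184.55, tolerance = 1 / 184)
  expect_equal(got[3], 185.32, tolerance = 1 / 185)
  expect_equal(got[4], 197.0, tolerance = 1 / 197)
})

test_that("noise-free performance is determined by the genotype groups", {
  cfg <- sim_config(n = c(national = 30), seed = 3,
                    effects = effect_model(sd = 1e-9))
  co <- simulate_study(cfg)
  mu <- 199.65 - 8.77 * (co$rs1815739 == "TT") -
    11.68 * (co$rs41274853 == "CC")
  expect_equal(co$wilks, mu, tolerance = 1e-6)
})

test_that("effect loci must be present in the cohort", {
  cfg <- sim_config(n = c(national = 10), seed = 5, effects = NULL)
  co <- simulate_genotypes(cfg, panel = wl_panel()[1:3, ])
  expect_error(simulate_performance(co, effect_model(), seed = 5),
               "absent")
})

test_that("enriched draws order the groups; pipeline round trip is exact", {
  set.seed(29)
  wins <- 0L
  for (i in 1:20) {
    cfg <- sim_config(seed = 2000L + i, effects = NULL)
    co <- simulate_genotypes(cfg)
    mw <- function(g) tgs_mean_from_counts(wrm_model(),
                                           counts_from_cohort(co, g))$mean
    if (mw("control") < mw("national") && mw("national") < mw("international"))
      wins <- wins + 1L
    if (i == 1) {
      # cohort-level mean TGS equals the count-route mean exactly
      s <- tgs(wrm_model(), co[co$group == "control", ])
      expect_equal(mean(s), mw("control"), tolerance = 1e-10)
    }
  }
  expect_gte(wins, 15L)
})

test_that("the packaged simulation config mirrors the study design", {
  cfg <- read_sim_config(seed = 11)
  expect_equal(cfg$n, c(control = 416L, national = 125L,
                        international = 67L))
  expect_true(cfg$enrichment)
  expect_equal(cfg$effects$baseline, 199.65)
  expect_equal(cfg$effects$shifts$rs1815739[["TT"]], -8.77)
  # same config + seed: identical cohorts whether built in code or from JSON
  in_code <- simulate_study(sim_config(seed = 11))
  expect_identical(simulate_study(cfg), in_code)
})

test_that("null draws reject the TGS t-test at the nominal rate", {
  set.seed(31)
  rej <- vapply(1:400, function(i) {
    cfg <- sim_config(n = c(control = 80, national = 80),
                      enrichment = FALSE, seed = 3000L + i, effects = NULL)
    co <- simulate_genotypes(cfg, panel = wl_panel()[c(1, 2, 4, 6, 10, 11), ])
    s <- tgs(wrm_model(), co)
    two_group_t(s[co$group == "national"], s[co$group == "control"])$p < 0.05
  }, NA)
  expect_true(abs(mean(rej) - 0.05) <= 0.035)
})
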