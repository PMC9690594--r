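# Score tables, the TGS formula, convolution distributions, WRM builder.

test_that("published score tables have the stated structure", {
  pwm <- pwm_model(); wrm <- wrm_model()
  expect_equal(nrow(pwm), 12L)
  expect_equal(nrow(wrm), 6L)
  expect_equal(attr(pwm, "scale"), 100 / 24)
  expect_equal(attr(wrm, "scale"), 100 / 12)
  expect_setequal(wrm$gene,
                  c("ACE", "ACTN3", "CHRNB3", "CNTFR", "MCT1", "PPARGC1A"))
  for (m in list(pwm, wrm)) {
    expect_true(all(m$s_het == 1L))
    expect_true(all(sort(c(m$s_hi, m$s_lo)) ==
                    rep(c(0L, 2L), each = nrow(m))))
    expect_true(all(m$s_hi + m$s_lo == 2L))
  }
  # PWM scores ACE II optimal; WRM flips it to DD (and CHRNB3 to GG)
  expect_equal(pwm$s_lo[pwm$gene == "ACE"], 2L)   # II
  expect_equal(wrm$s_hi[wrm$gene == "ACE"], 2L)   # DD
  expect_equal(pwm$s_hi[pwm$gene == "CHRNB3"], 2L)  # AA
  expect_equal(wrm$s_lo[wrm$gene == "CHRNB3"], 2L)  # GG
})

test_that("individual TGS is the scaled score sum, order-invariant", {
  wrm <- wrm_model()
  opt <- c(ACE = "DD", ACTN3 = "RR", CHRNB3 = "GG", CNTFR = "TT",
           MCT1 = "TT", PPARGC1A = "AA")
  worst <- c(ACE = "II", ACTN3 = "XX", CHRNB3 = "AA", CNTFR = "CC",
             MCT1 = "AA", PPARGC1A = "GG")
  hets <- c(ACE = "ID", ACTN3 = "RX", CHRNB3 = "GA", CNTFR = "CT",
            MCT1 = "TA", PPARGC1A = "GA")
  expect_equal(as.numeric(tgs(wrm, opt)), 100)
  expect_equal(as.numeric(tgs(wrm, worst)), 0)
  # five intermediate + one lo-scoring het combination: 100 * 5/12
  mixed <- hets; mixed["ACE"] <- "II"
  expect_equal(as.numeric(tgs(wrm, mixed)), 100 * 5 / 12, tolerance = 1e-12)
  expect_equal(as.numeric(tgs(wrm, hets)), 50)
  scrambled <- hets[c(4, 2, 6, 1, 3, 5)]
  expect_equal(as.numeric(tgs(wrm, scrambled)), as.numeric(tgs(wrm, hets)))
  expect_error(tgs(wrm, hets[-1]), "lacks table loci")
  expect_error(tgs(wrm, replace(hets, 1, NA)), "missing")
})

test_that("cohort TGS excludes incomplete individuals with a count", {
  co <- small_cohort()
  co$rs4341[2] <- NA
  s <- tgs(wrm_model(), co)
  expect_true(is.na(s[2]))
  expect_equal(attr(s, "n_missing"), 1L)
  expect_equal(sum(!is.na(s)), 5L)
})

test_that("count-mean TGS reproduces the published group means", {
  f <- fixture_tables()
  wrm <- wrm_model()
  expect_equal(round(tgs_mean_from_counts(wrm, f$controls)$mean, 2), 32.93)
  nat <- derive_national(f$weightlifters, f$international)
  expect_equal(round(tgs_mean_from_counts(wrm, nat)$mean, 2), 35.53)
  # single-individual cohort: count mean equals the individual TGS
  co <- small_cohort()[1, ]
  cc <- counts_from_cohort(co, "national")
  expect_equal(tgs_mean_from_counts(wrm, cc)$mean,
               as.numeric(tgs(wrm, co)), tolerance = 1e-12)
})

test_that("convolution pmf is exact: hand case, linearity, Monte Carlo", {
  # two-locus hand convolution: P(0)=P(2)=0.5 at locus 1, P(1)=1 at locus 2
  toy <- count_table(data.frame(rs_id = c("rs4341", "rs1815739"),
                                n_hi = c(1L, 0L), n_het = c(0L, 2L),
                                n_lo = c(1L, 0L)), "toy")
  mod <- score_table(c(ACE = "DD", ACTN3 = "CC"), "toy2")
  d <- tgs_distribution(mod, toy)
  expect_equal(d$pmf$prob[d$pmf$sum == 1], 0.5)
  expect_equal(d$pmf$prob[d$pmf$sum == 3], 0.5)
  expect_equal(sum(d$pmf$prob), 1, tolerance = 1e-12)
  # fixture controls: pmf mean equals the linearity mean to 1e-10
  f <- fixture_tables()
  wrm <- wrm_model()
  dc <- tgs_distribution(wrm, f$controls)
  expect_equal(dc$mean, tgs_mean_from_counts(wrm, f$controls)$mean,
               tolerance = 1e-10)
  expect_equal(sum(dc$pmf$prob), 1, tolerance = 1e-12)
  # Monte Carlo oracle: empirical score-sum distribution at large n
  set.seed(11)
  n <- 2e5
  sums <- numeric(n)
  for (rs in wrm$rs_id) {
    row <- f$controls[f$controls$rs_id == rs, ]
    m <- wrm[wrm$rs_id == rs, ]
    sums <- sums + sample(c(m$s_hi, m$s_het, m$s_lo), n, replace = TRUE,
                          prob = c(row$n_hi, row$n_het, row$n_lo))
  }
  emp <- tabulate(sums + 1L, nbins = 13L) / n
  tv <- 0.5 * sum(abs(emp - dc$pmf$prob))
  expect_lt(tv, 0.005)
})

test_that("pmf mean and variance track Monte Carlo for random score tables", {
  set.seed(23)
  f <- fixture_tables()
  genes <- c("ACE", "ALDH2", "CKM", "FTO", "IGF2", "TRHR")
  for (rep in 1:5) {
    pick <- sample(genes, 4)
    optimal <- vapply(pick, function(g) {
      loc <- locus_info(g)
      sample(c(loc$gt_hi, loc$gt_lo), 1)
    }, "")
    mod <- score_table(optimal, "random")
    d <- tgs_distribution(mod, f$weightlifters)
    mu <- sum(d$pmf$sum * d$pmf$prob)
    v <- sum((d$pmf$sum - mu)^2 * d$pmf$prob)
    n <- 5e4
    sims <- numeric(n)
    for (rs in mod$rs_id) {
      row <- f$weightlifters[f$weightlifters$rs_id == rs, ]
      m <- mod[mod$rs_id == rs, ]
      sims <- sims + sample(c(m$s_hi, m$s_het, m$s_lo), n, replace = TRUE,
                            prob = c(row$n_hi, row$n_het, row$n_lo))
    }
    expect_equal(mean(sims), mu, tolerance = 0.02)
    expect_equal(var(sims), v, tolerance = 0.05)
  }
})

test_that("threshold proportions behave at the edges and compare groups", {
  f <- fixture_tables()
  d <- tgs_distribution(wrm_model(), f$controls)
  expect_equal(proportion_at_least(d, 0), 1, tolerance = 1e-12)
  expect_equal(proportion_at_least(d, 100), d$pmf$prob[13])
  expect_error(proportion_at_least(d, 101), "threshold")
  p50 <- proportion_at_least(d, 50)
  expect_true(p50 > 0 && p50 < 1)
  cmp <- compare_threshold_proportions(c(55, 60, 40, 45), c(40, 30, 55, 20))
  expect_equal(cmp$prop_a, 0.5)
  expect_equal(cmp$prop_b, 0.25)
})

test_that("build_wrm re-derives the published model from the counts", {
  f <- fixture_tables()
  scr <- case_control_screen(f[c("weightlifters", "international")],
                             f$controls)
  wrm <- build_wrm(scr, f[c("weightlifters", "international")], f$controls)
  ref <- wrm_model()
  got <- wrm[order(wrm$rs_id), c("gene", "s_hi", "s_het", "s_lo")]
  want <- ref[order(ref$rs_id), c("gene", "s_hi", "s_het", "s_lo")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  expect_equal(attr(wrm, "scale"), 100 / 12)
  aud <- attr(wrm, "selection")
  expect_setequal(aud$triggered_by[aud$gene %in% c("ACTN3", "CNTFR")],
                  "international")
  # degenerate screens
  expect_error(build_wrm(scr, f[c("weightlifters", "international")],
                         f$controls, alpha = 1e-9), "empty model")
  null_scr <- case_control_screen(list(controls2 = f$controls), f$controls)
  expect_error(build_wrm(null_scr, list(controls2 = f$controls),
                         f$controls), "empty model")
})

test_that("score tables round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_score_table(wrm_model(), path)
  back <- read_score_table(path)
  expect_equal(as.data.frame(back), as.data.frame(wrm_model()))
  expect_equal(attr(back, "model_name"), "WRM")
})
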