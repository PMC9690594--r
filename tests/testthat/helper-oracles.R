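# Independent textbook-formula oracles used to pin the package's statistics.

# Pearson chi-square on a 2 x k table from first principles
oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

# pooled-variance two-sample t from the textbook formula
oracle_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# a tiny complete cohort over the six WRM loci (canonical labels)
small_cohort <- function() {
  make_cohort(
    id = c("w1", "w2", "w3", "c1", "c2", "c3"),
    group = c(rep("national", 3), rep("control", 3)),
    genotypes = data.frame(
      rs4341     = c("DD", "ID", "II", "II", "ID", "II"),
      rs1815739  = c("RR", "RX", "XX", "TT", "CT", "TT"),
      rs4950     = c("GG", "GA", "AA", "AA", "AA", "GA"),
      rs41274853 = c("TT", "CT", "CC", "CC", "CC", "CT"),
      rs1049434  = c("TT", "TA", "AA", "AA", "AA", "TA"),
      rs8192678  = c("AA", "GA", "GG", "GG", "GG", "GA"),
      stringsAsFactors = FALSE),
    wilks = c(210, 195, 180, NA, NA, NA))
}

fixture_tables <- function() wl_counts()
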