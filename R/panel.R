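# Locus panel: twelve autosomal strength/power candidate polymorphisms.
#
# Genotype labels are canonicalized per locus: the "hi" allele is the one
# listed first in the polymorphism notation (e.g. C in "C > T"), genotypes are
# ordered (hi-homozygote, heterozygote, lo-homozygote), and common synonym
# spellings (ACTN3 R/X protein alleles, IGF2 opposite-strand G/A) resolve to
# the canonical labels. Heterozygotes are unordered: "GA" and "AG" are the
# same genotype.

# allele-level synonym maps, keyed by rs id
.wl_allele_synonyms <- list(
  rs1815739 = c(R = "C", X = "T"),   # ACTN3 R577X protein notation
  rs680     = c(G = "C", A = "T")    # IGF2: opposite-strand reporting
)

#' Panel of the twelve weightlifting-study polymorphisms
#'
#' Returns the locus panel used throughout the package: twelve autosomal SNPs
#' (the ACE I/D indel is tagged by rs4341, in perfect LD with it) previously
#' associated with strength or power phenotypes. Each locus carries its two
#' allele labels and the three canonical genotype labels in the order
#' (hi-homozygote, heterozygote, lo-homozygote), plus the per-locus
#' orientation of the dominant model used in the published count table
#' (`dominant_split`): `"hi"` means dominant compares the hi-homozygote
#' against carriers of the lo allele; `"hi_het"` means it compares hi-allele
#' carriers against the lo-homozygote (only ACTN3 uses the latter).
#'
#' @return A data.frame with one row per locus and columns `gene`, `rs_id`,
#'   `allele_hi`, `allele_lo`, `gt_hi`, `gt_het`, `gt_lo`, `dominant_split`.
#' @examples
#' wl_panel()
#' @export
wl_panel <- function() {
  p <- data.frame(
    gene      = c("ACE", "ACTN3", "ALDH2", "CHRNB3", "CKM", "CNTFR",
                  "FTO", "GALNTL6", "IGF2", "MCT1", "PPARGC1A", "TRHR"),
    rs_id     = c("rs4341", "rs1815739", "rs671", "rs4950", "rs8111989",
                  "rs41274853", "rs9939609", "rs558129", "rs680",
                  "rs1049434", "rs8192678", "rs7832552"),
    allele_hi = c("D", "C", "G", "A", "A", "C", "T", "C", "C", "A", "A", "T"),
    allele_lo = c("I", "T", "A", "G", "G", "T", "A", "T", "T", "T", "G", "C"),
    gt_hi     = c("DD", "CC", "GG", "AA", "AA", "CC", "TT", "CC", "CC", "AA", "AA", "TT"),
    gt_het    = c("ID", "CT", "GA", "GA", "GA", "CT", "TA", "CT", "CT", "TA", "GA", "CT"),
    gt_lo     = c("II", "TT", "AA", "GG", "GG", "TT", "AA", "TT", "TT", "TT", "GG", "CC"),
    dominant_split = c("hi", "hi_het", "hi", "hi", "hi", "hi",
                       "hi", "hi", "hi", "hi", "hi", "hi"),
    stringsAsFactors = FALSE
  )
  class(p) <- c("wl_panel", "data.frame")
  p
}

#' Look up one locus of the panel
#'
#' @param locus A gene symbol or rs id.
#' @param panel A locus panel, by default [wl_panel()].
#' @return The matching one-row data.frame.
#' @export
locus_info <- function(locus, panel = wl_panel()) {
  i <- match(locus, panel$gene)
  if (is.na(i)) i <- match(locus, panel$rs_id)
  if (is.na(i)) stop("unknown locus: ", locus, call. = FALSE)
  panel[i, , drop = FALSE]
}

#' Canonicalize genotype labels for one locus
#'
#' Resolves a vector of genotype spellings to the locus's canonical labels.
#' Matching is case-insensitive and allele-order-insensitive, and applies the
#' locus's allele synonym map (ACTN3 `RR`/`RX`/`XX` resolve to `CC`/`CT`/`TT`;
#' IGF2 opposite-strand `GG`/`GA`/`AA` resolve to `CC`/`CT`/`TT`). Empty
#' strings and `NA` are treated as missing and returned as `NA`.
#'
#' @param labels Character vector of genotype spellings.
#' @inheritParams locus_info
#' @return Character vector of canonical labels, `NA` for missing.
#' @examples
#' canonical_genotype(c("RX", "xx", "CC"), "ACTN3")
#' @export
canonical_genotype <- function(labels, locus, panel = wl_panel()) {
  loc <- locus_info(locus, panel)
  syn <- .wl_allele_synonyms[[loc$rs_id]]
  out <- rep(NA_character_, length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (is.na(lab) || !nzchar(trimws(lab))) next
    a <- strsplit(toupper(trimws(lab)), "")[[1]]
    if (length(a) != 2L)
      stop("malformed genotype label '", lab, "' for locus ", loc$gene,
           call. = FALSE)
    if (!is.null(syn)) {
      hit <- a %in% names(syn)
      a[hit] <- syn[a[hit]]
    }
    n_hi <- sum(a == loc$allele_hi)
    n_lo <- sum(a == loc$allele_lo)
    if (n_hi + n_lo != 2L)
      stop("unknown genotype label '", lab, "' for locus ", loc$gene,
           " (alleles ", loc$allele_hi, "/", loc$allele_lo, ")",
           call. = FALSE)
    out[i] <- if (n_hi == 2L) loc$gt_hi else if (n_lo == 2L) loc$gt_lo else loc$gt_het
  }
  out
}
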