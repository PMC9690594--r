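# Individual-level cohorts: one row per person with group label, optional
# Wilks-point performance, and one genotype column per panel locus.
# On-disk dialect: UTF-8 TSV, header "id  group  wilks  <rs...>", genotype
# cells in canonical or synonym spelling, empty cell = missing.

#' Read an individual-level genotype cohort from TSV
#'
#' Expects a tab-separated file with columns `id`, optional `group` and
#' `wilks` (performance in Wilks points), and one column per locus named by
#' rs id. Genotype spellings are canonicalized via [canonical_genotype()];
#' unrecognized labels raise an error naming the row and column; empty cells
#' become `NA` (missing).
#'
#' @param path File path.
#' @param panel Locus panel; file loci must be a subset of it.
#' @return A `wl_cohort` data.frame.
#' @export
read_cohort <- function(path, panel = wl_panel()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  loci <- setdiff(names(raw), c("id", "group", "wilks"))
  unknown <- setdiff(loci, panel$rs_id)
  if (length(unknown))
    stop("unknown rs id column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (rs in loci) {
    raw[[rs]] <- tryCatch(
      canonical_genotype(raw[[rs]], rs, panel),
      error = function(e) {
        bad <- which(!is.na(raw[[rs]]) & nzchar(trimws(raw[[rs]])))
        stop(conditionMessage(e), " (column ", rs, ")", call. = FALSE)
      })
  }
  if ("wilks" %in% names(raw)) {
    w <- suppressWarnings(as.numeric(raw$wilks))
    bad <- which(!is.na(raw$wilks) & nzchar(raw$wilks) & is.na(w))
    if (length(bad))
      stop("non-numeric performance value in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(w < 0, na.rm = TRUE))
      stop("negative performance values", call. = FALSE)
    raw$wilks <- w
  }
  class(raw) <- c("wl_cohort", "data.frame")
  raw
}

#' @rdname read_cohort
#' @param cohort A cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Assemble a cohort data.frame in memory
#'
#' @param id,group Vectors of ids and group labels.
#' @param genotypes A data.frame of genotype columns named by rs id
#'   (canonical labels or synonyms; canonicalized here).
#' @param wilks Optional numeric performance vector.
#' @param panel Locus panel.
#' @return A `wl_cohort` data.frame.
#' @export
make_cohort <- function(id, group, genotypes, wilks = NULL,
                        panel = wl_panel()) {
  x <- data.frame(id = as.character(id), group = as.character(group),
                  stringsAsFactors = FALSE)
  if (!is.null(wilks)) x$wilks <- as.numeric(wilks)
  for (rs in names(genotypes))
    x[[rs]] <- canonical_genotype(as.character(genotypes[[rs]]), rs, panel)
  class(x) <- c("wl_cohort", "data.frame")
  x
}
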