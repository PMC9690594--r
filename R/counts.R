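# Genotype count tables: one row per locus, integer counts of the three
# canonical genotypes within one group. The packaged fixture holds the
# published counts for controls (n=416), all weightlifters (n=192) and
# international-level weightlifters (n=67).

#' Construct a genotype count table
#'
#' @param counts A data.frame with columns `rs_id`, `n_hi`, `n_het`, `n_lo`
#'   (non-negative integers), one row per locus.
#' @param group Group label.
#' @param panel Locus panel the rs ids must belong to.
#' @return A `wl_counts` data.frame (columns `gene`, `rs_id`, `n_hi`,
#'   `n_het`, `n_lo`) with attributes `group` and `n_total`.
#' @export
count_table <- function(counts, group, panel = wl_panel()) {
  stopifnot(all(c("rs_id", "n_hi", "n_het", "n_lo") %in% names(counts)))
  i <- match(counts$rs_id, panel$rs_id)
  if (anyNA(i))
    stop("unknown rs id(s): ", paste(counts$rs_id[is.na(i)], collapse = ", "),
         call. = FALSE)
  x <- data.frame(gene = panel$gene[i], rs_id = counts$rs_id,
                  n_hi = as.integer(counts$n_hi),
                  n_het = as.integer(counts$n_het),
                  n_lo = as.integer(counts$n_lo),
                  stringsAsFactors = FALSE)
  if (any(x$n_hi < 0 | x$n_het < 0 | x$n_lo < 0))
    stop("negative genotype counts", call. = FALSE)
  tot <- unique(x$n_hi + x$n_het + x$n_lo)
  if (length(tot) != 1L)
    stop("per-locus totals differ within group '", group,
         "': a complete table has the same n at every locus", call. = FALSE)
  structure(x, group = group, n_total = tot,
            class = c("wl_counts", "data.frame"))
}

#' @export
print.wl_counts <- function(x, ...) {
  cat("Genotype counts: group '", attr(x, "group"), "', n = ",
      attr(x, "n_total"), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Published genotype counts for weightlifters and controls
#'
#' Loads the packaged per-locus genotype counts of the twelve-SNP panel in
#' the three published groups: 416 controls, 192 weightlifters (all levels)
#' and the 67 international-level weightlifters among them. The 125
#' national-level lifters are obtained with [derive_national()].
#'
#' @param group One of `"controls"`, `"weightlifters"`, `"international"`,
#'   or `NULL` (default) to return a named list of all three tables.
#' @return A `wl_counts` table, or a named list of the three tables.
#' @examples
#' wl_counts("controls")
#' @export
wl_counts <- function(group = NULL) {
  path <- system.file("extdata", "table2_counts.tsv", package = "tgslift",
                      mustWork = TRUE)
  tabs <- read_count_table(path)
  if (is.null(group)) return(tabs)
  if (!group %in% names(tabs))
    stop("unknown group '", group, "'; fixture groups: ",
         paste(names(tabs), collapse = ", "), call. = FALSE)
  tabs[[group]]
}

#' Derive the national-level count table by subtraction
#'
#' The published table reports all weightlifters and the international-level
#' subgroup; the national-level group is their per-cell difference.
#'
#' @param all_table,sub_table `wl_counts` tables over the same loci, with
#'   `sub_table` a subgroup of `all_table`.
#' @param group Label for the derived table.
#' @return A `wl_counts` table; for the fixture, n = 125.
#' @export
derive_national <- function(all_table, sub_table, group = "national") {
  i <- match(all_table$rs_id, sub_table$rs_id)
  if (anyNA(i) || nrow(all_table) != nrow(sub_table))
    stop("tables cover different loci", call. = FALSE)
  d <- data.frame(rs_id = all_table$rs_id,
                  n_hi = all_table$n_hi - sub_table$n_hi[i],
                  n_het = all_table$n_het - sub_table$n_het[i],
                  n_lo = all_table$n_lo - sub_table$n_lo[i])
  if (any(d$n_hi < 0 | d$n_het < 0 | d$n_lo < 0))
    stop("inconsistent tables: subtraction yields negative counts",
         call. = FALSE)
  count_table(d, group)
}

#' Read / write genotype count tables as TSV
#'
#' The on-disk format is long: columns `group`, `rs_id`, `genotype`, `count`,
#' with genotype labels canonical or synonym spellings for the panel.
#'
#' @param path File path.
#' @param panel Locus panel.
#' @return `read_count_table()`: a named list of `wl_counts` tables, one per
#'   group in file order.
#' @export
read_count_table <- function(path, panel = wl_panel()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "rs_id", "genotype", "count") %in% names(raw)))
  out <- list()
  for (g in unique(raw$group)) {
    sub <- raw[raw$group == g, ]
    rows <- lapply(split(sub, sub$rs_id), function(s) {
      loc <- locus_info(s$rs_id[1], panel)
      canon <- canonical_genotype(s$genotype, s$rs_id[1], panel)
      cnt <- integer(3)
      names(cnt) <- c(loc$gt_hi, loc$gt_het, loc$gt_lo)
      cnt[canon] <- s$count
      data.frame(rs_id = s$rs_id[1], n_hi = cnt[1], n_het = cnt[2],
                 n_lo = cnt[3])
    })
    d <- do.call(rbind, rows)
    d <- d[match(panel$rs_id[panel$rs_id %in% d$rs_id], d$rs_id), ]
    out[[g]] <- count_table(d, g, panel)
  }
  out
}

#' @rdname read_count_table
#' @param tables A `wl_counts` table or list of them.
#' @export
write_count_table <- function(tables, path, panel = wl_panel()) {
  if (inherits(tables, "wl_counts")) tables <- list(tables)
  rows <- lapply(tables, function(tab) {
    i <- match(tab$rs_id, panel$rs_id)
    data.frame(group = attr(tab, "group"),
               rs_id = rep(tab$rs_id, each = 3L),
               genotype = as.vector(rbind(panel$gt_hi[i], panel$gt_het[i],
                                          panel$gt_lo[i])),
               count = as.vector(rbind(tab$n_hi, tab$n_het, tab$n_lo)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate genotype counts from an individual-level cohort
#'
#' Missing genotypes are excluded; counts sum to the number of genotyped
#' individuals in the group at each locus. When per-locus totals differ
#' because of missingness the table is still returned, with `n_total` the
#' maximum (group size); validity checks that require a constant total are
#' bypassed.
#'
#' @param cohort A cohort data.frame as returned by [read_cohort()] or
#'   [simulate_study()].
#' @param group Group label to tabulate (must appear in `cohort$group`).
#' @param panel Locus panel; only panel loci present in the cohort are used.
#' @return A `wl_counts` table.
#' @export
counts_from_cohort <- function(cohort, group, panel = wl_panel()) {
  if (!group %in% cohort$group)
    stop("unknown group '", group, "'", call. = FALSE)
  sub <- cohort[cohort$group == group, , drop = FALSE]
  loci <- intersect(panel$rs_id, names(cohort))
  if (length(loci) == 0L) stop("cohort has no panel locus columns", call. = FALSE)
  rows <- lapply(loci, function(rs) {
    loc <- locus_info(rs, panel)
    g <- sub[[rs]]
    data.frame(rs_id = rs,
               n_hi = sum(g == loc$gt_hi, na.rm = TRUE),
               n_het = sum(g == loc$gt_het, na.rm = TRUE),
               n_lo = sum(g == loc$gt_lo, na.rm = TRUE))
  })
  d <- do.call(rbind, rows)
  tot <- d$n_hi + d$n_het + d$n_lo
  x <- data.frame(gene = panel$gene[match(d$rs_id, panel$rs_id)],
                  rs_id = d$rs_id, n_hi = d$n_hi, n_het = d$n_het,
                  n_lo = d$n_lo, stringsAsFactors = FALSE)
  structure(x, group = group, n_total = nrow(sub),
            n_genotyped = stats::setNames(tot, d$rs_id),
            class = c("wl_counts", "data.frame"))
}
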