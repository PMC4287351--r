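## Read-density enrichment: density = reads per bp of an interval; fold
## enrichment of the ncRNA-containing interval over a reference intron.

#' Count reads overlapping target intervals
#'
#' A read counts toward a target when it overlaps it by at least 1 bp;
#' strand is ignored by default (tiling-array and RNA-seq provenance is
#' mixed), set `strand_aware = TRUE` to require matching strand.
#'
#' @param reads `GRanges` of read intervals, or BED path.
#' @param targets `GRanges` of target intervals, or BED path.
#' @param strand_aware logical (default `FALSE`).
#' @return integer vector of counts, one per target.
#' @export
count_reads <- function(reads, targets, strand_aware = FALSE) {
  if (is.character(reads)) reads <- read_loci_bed(reads)
  if (is.character(targets)) targets <- read_loci_bed(targets)
  if (!length(reads)) return(integer(length(targets)))
  miss <- setdiff(as.character(unique(seqnames(targets))),
                  as.character(unique(seqnames(reads))))
  if (length(miss))
    stop("target sequence id(s) absent from reads: ",
         paste(miss, collapse = ", "), call. = FALSE)
  countOverlaps(targets, reads, minoverlap = 1L,
                ignore.strand = !strand_aware)
}

#' Per-interval read densities
#'
#' @param counts `data.frame` with columns `interval_id`, `count`, `length`
#'   (e.g. from [read_counts_tsv()] or [simulate_read_counts()]).
#' @return the table with a `density` column (reads per bp) appended.
#' @export
density_table <- function(counts) {
  need <- c("interval_id", "count", "length")
  if (!all(need %in% names(counts)))
    stop("'counts' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(counts$length <= 0))
    stop("interval lengths must be > 0", call. = FALSE)
  counts$density <- counts$count / counts$length
  counts
}

#' Fold enrichment of one interval's read density over another's
#'
#' `fold_enrichment(a, b)` returns `density(a) / density(b)`. Inputs may be
#' single-row records (lists or data.frame rows with `count` and `length`)
#' or raw densities.
#'
#' @param a,b density records or numeric densities.
#' @return the density ratio (single numeric).
#' @examples
#' # ncRNA-containing interval vs the preceding host intron:
#' fold_enrichment(list(count = 2435, length = 353),
#'                 list(count = 978, length = 683))   # ~4.82
#' @export
fold_enrichment <- function(a, b) {
  dens <- function(x) {
    if (is.numeric(x) && length(x) == 1L) return(x)
    x <- as.list(x)
    if (is.null(x$count) || is.null(x$length))
      stop("density records need 'count' and 'length'", call. = FALSE)
    x$count / x$length
  }
  db <- dens(b)
  if (db <= 0)
    stop("reference interval has zero read density; fold enrichment undefined",
         call. = FALSE)
  dens(a) / db
}

#' Fold enrichment of every interval over a named reference interval
#'
#' @param counts counts table (see [density_table()]).
#' @param reference_id `interval_id` of the reference interval.
#' @return density table with a `fold_vs_reference` column.
#' @export
fold_enrichment_table <- function(counts, reference_id) {
  d <- density_table(counts)
  ref <- d[d$interval_id == reference_id, , drop = FALSE]
  if (nrow(ref) != 1L)
    stop("reference interval '", reference_id, "' not found exactly once",
         call. = FALSE)
  d$fold_vs_reference <- vapply(seq_len(nrow(d)), function(i)
    fold_enrichment(d$density[i], ref$density), numeric(1))
  d
}
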