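## Format boundaries: FASTA and BED via Biostrings/rtracklayer, GFF3 via
## rtracklayer (with deterministic headers), simple commented TSV tables.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return `DNAStringSet` named by sequence id (first whitespace-delimited
#'   token of the header).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome file not found: ", path, call. = FALSE)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read candidate loci (or reads) from BED6
#'
#' BED is 0-based half-open; rtracklayer converts to the 1-based closed
#' convention used internally.
#'
#' @param path BED file.
#' @return `GRanges` with `name` (and `score` where present).
#' @export
read_loci_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  tryCatch(rtracklayer::import(path, format = "bed"),
           error = function(e)
             stop("malformed BED '", path, "': ", conditionMessage(e),
                  call. = FALSE))
}

#' Write loci to BED6
#'
#' @param loci `GRanges` with `name` (and optionally `score`).
#' @param path output file.
#' @param seed optional seed recorded as a leading comment line.
#' @return `path` invisibly.
#' @export
write_loci_bed <- function(loci, path, seed = NULL) {
  if (is.null(loci$score)) loci$score <- rep(0L, length(loci))
  rtracklayer::export(loci, path, format = "bed")
  if (!is.null(seed))
    writeLines(c(paste0("# seed: ", seed), readLines(path)), path)
  invisible(path)
}

## GFF3 writer with deterministic headers: rtracklayer stamps the file
## with its version and the date, which breaks byte-level reproducibility
## of seeded runs, so those lines are stripped and the seed recorded.
write_gff3 <- function(gr, path, seed = NULL) {
  rtracklayer::export(gr, path, format = "gff3")
  ln <- readLines(path)
  ln <- ln[!grepl("^##(source-version|date)", ln)]
  if (!is.null(seed))
    ln <- append(ln, paste0("# seed: ", seed), after = 1L)
  writeLines(ln, path)
  invisible(path)
}

#' Read a per-interval counts table
#'
#' Tab-separated with header columns `interval_id`, `count`, `length`;
#' lines starting with `#` are ignored.
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("interval_id", "count", "length")
  if (!all(need %in% names(d)))
    stop("counts TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

## Commented-header TSV writer used for truth tables, counts and reports.
write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
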