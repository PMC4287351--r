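## Signature-motif validation of candidate RPR/MRP RNAs.

#' Find all matches of a degenerate IUPAC motif in a DNA sequence
#'
#' Returns every (possibly overlapping) 1-based start position where `seq`
#' matches `motif` under IUPAC expansion (e.g. `R` matches `A` or `G`).
#' Matching is delegated to [Biostrings::matchPattern()] with
#' `fixed = FALSE`.
#'
#' @param motif IUPAC string.
#' @param seq DNA string (may contain `N`, which matches any base).
#' @return sorted integer vector of match starts (possibly empty).
#' @examples
#' match_iupac("GARAR", "TTGAGAGTT")  # R matches A or G
#' @export
match_iupac <- function(motif, seq) {
  motif <- check_iupac(motif)
  seq <- check_dna(seq)
  if (nchar(seq) < nchar(motif)) return(integer(0))
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                fixed = FALSE)
  sort(BiocGenerics::start(m))
}

#' Define a signature motif set
#'
#' A named collection of IUPAC motifs with required-set logic: `"all"`
#' requires every motif to match, `"any_k"` requires at least `k`. With
#' `ordered = TRUE` the motifs must additionally occur in the listed order
#' (some choice of non-overlapping hits with increasing positions).
#'
#' @param motifs named character vector of IUPAC motifs.
#' @param logic `"all"` (default) or `"any_k"`.
#' @param k minimum number of matching motifs when `logic = "any_k"`.
#' @param ordered require in-order occurrence (default `FALSE`; presence
#'   alone is checked).
#' @return object of class `"signature_set"`.
#' @export
signature_set <- function(motifs, logic = c("all", "any_k"), k = NULL,
                          ordered = FALSE) {
  logic <- match.arg(logic)
  if (!length(motifs)) stop("'motifs' must be non-empty", call. = FALSE)
  if (is.null(names(motifs)) || any(!nzchar(names(motifs))))
    stop("'motifs' must be named", call. = FALSE)
  motifs <- vapply(motifs, check_iupac, character(1))
  if (logic == "any_k") {
    if (is.null(k) || k < 1L || k > length(motifs))
      stop("'k' must be in [1, length(motifs)] for any_k logic", call. = FALSE)
  } else k <- length(motifs)
  structure(list(motifs = motifs, logic = logic, k = as.integer(k),
                 ordered = isTRUE(ordered)),
            class = "signature_set")
}

#' Verify one candidate sequence against a signature set
#'
#' @param seq DNA string of the candidate RNA gene.
#' @param sigs a [signature_set()]; default: the package's MRP-style set
#'   (GARAR plus placeholder mCR-I / mCR-V consensi).
#' @return list with `pass` flag, `missing` (names of required motifs with
#'   no hit), and `report`, a `data.frame` (motif, pattern, n_hits,
#'   first_hit).
#' @export
verify_candidate <- function(seq, sigs = signature_set(polr3_defaults()$signatures)) {
  stopifnot(inherits(sigs, "signature_set"))
  hits <- lapply(sigs$motifs, match_iupac, seq = seq)
  n_hits <- vapply(hits, length, integer(1))
  report <- data.frame(
    motif = names(sigs$motifs), pattern = unname(sigs$motifs),
    n_hits = unname(n_hits),
    first_hit = vapply(hits, function(h)
      if (length(h)) h[1] else NA_integer_, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  present <- n_hits > 0L
  pass <- sum(present) >= sigs$k
  if (pass && sigs$ordered) {
    ## greedy left-to-right: each motif must start after the previous
    ## motif's chosen hit ends
    pos <- 0L
    for (i in seq_along(hits)) {
      ok <- hits[[i]][hits[[i]] > pos]
      if (!length(ok)) { pass <- FALSE; break }
      pos <- ok[1] + nchar(sigs$motifs[i]) - 1L
    }
  }
  list(pass = pass,
       missing = names(sigs$motifs)[!present],
       report = report)
}

#' Verify a set of candidate loci against a signature set
#'
#' Extracts each locus's sense-strand sequence from the genome and applies
#' [verify_candidate()].
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param loci `GRanges` with `name`, or BED6 path.
#' @param sigs a [signature_set()].
#' @return `data.frame`: `locus_id`, `pass`, one logical column per motif,
#'   and `missing` (comma-separated names).
#' @export
verify_candidates <- function(genome, loci,
                              sigs = signature_set(polr3_defaults()$signatures)) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(loci)) loci <- read_loci_bed(loci)
  ids <- loci$name %||% as.character(seq_along(loci))
  rows <- lapply(seq_along(loci), function(i) {
    sq <- locus_sequences(genome, as.character(seqnames(loci)[i]),
                          start(loci)[i], end(loci)[i],
                          as.character(strand(loci)[i]), 0L, 0L)
    v <- verify_candidate(sq$locus, sigs)
    out <- data.frame(locus_id = ids[i], pass = v$pass,
                      stringsAsFactors = FALSE)
    for (m in v$report$motif)
      out[[m]] <- v$report$n_hits[v$report$motif == m] > 0L
    out$missing <- paste(v$missing, collapse = ",")
    out
  })
  do.call(rbind, rows)
}
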