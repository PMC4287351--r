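## Promoter-architecture scanning: PSE, positioned TATA, poly-T terminator,
## internal A-box/B-box, and the assembled pol III verdict.

#' Best PWM hit within a window of allowed starts
#'
#' Scores every window whose 1-based start lies in `window` and returns the
#' highest-scoring hit at or above `threshold`; ties are broken in favour of
#' the smaller start.
#'
#' @param pwm a [`pwm`][build_pwm()].
#' @param seq DNA string (sense strand of the scanned region).
#' @param threshold minimum score in bits.
#' @param window inclusive pair of allowed 1-based window starts; default
#'   all valid starts.
#' @return list with `start`, `score`, `length`, or `NULL` when no window
#'   reaches the threshold.
#' @export
scan_best_hit <- function(pwm, seq, threshold, window = NULL) {
  seq <- check_dna(seq)
  max_start <- nchar(seq) - pwm$length + 1L
  if (is.null(window)) window <- c(1L, max_start)
  if (length(window) != 2L || window[1] > window[2])
    stop("'window' must be a non-empty inclusive start pair", call. = FALSE)
  starts <- seq.int(max(1L, window[1]), min(max_start, window[2]))
  if (!length(starts))
    stop(sprintf("empty scan window [%d, %d] for sequence of length %d",
                 window[1], window[2], nchar(seq)), call. = FALSE)
  sc <- score_all_windows(pwm, seq, starts)
  ok <- sc >= threshold
  if (!any(ok)) return(NULL)
  best <- which.max(sc[ok])       # which.max keeps the smallest start on ties
  list(start = starts[ok][best], score = unname(sc[ok][best]),
       length = pwm$length)
}

#' Scan for a PSE upstream of a locus
#'
#' `upstream_seq` is the sense-strand sequence ending at the base
#' immediately before the locus's first base. The PSE is searched where its
#' first base lies `pse_search_window` nt upstream of the locus start
#' (distance = locus start minus PSE start, in sense-strand coordinates).
#'
#' @param upstream_seq sense-strand DNA ending just before the locus start.
#' @param model a [`promoter_model`][promoter_model()].
#' @return list with `start` (1-based in `upstream_seq`), `dist` (nt from
#'   PSE first base to locus first base), `score`, `length`; or `NULL`.
#' @export
scan_pse <- function(upstream_seq, model) {
  U <- nchar(upstream_seq)
  w <- model$pse_search_window
  need <- w[2]
  if (U < need)
    stop(sprintf("upstream context too short for PSE search: %d nt given, %d required",
                 U, need), call. = FALSE)
  ## distance d maps to string start s = U - d + 1
  starts <- c(U - w[2] + 1L, U - w[1] + 1L)
  hit <- scan_best_hit(model$pse, upstream_seq, model$pse_threshold, starts)
  if (is.null(hit)) return(NULL)
  hit$dist <- U - hit$start + 1L
  hit
}

#' Scan for a positionally constrained TATA box
#'
#' Scans the whole upstream sequence for TATA hits at or above the model
#' threshold. The gap of a hit is the number of bases strictly between the
#' last base of the TATA match and the locus's first base. If any hit's gap
#' falls in the model's `tata_offset_window` (inclusive), the best such hit
#' is returned with `positioned = TRUE`; otherwise the best hit anywhere is
#' returned with `positioned = FALSE`.
#'
#' @param upstream_seq sense-strand DNA ending just before the locus start.
#' @param model a [`promoter_model`][promoter_model()].
#' @return list with `hit` (as in [scan_best_hit()], plus `gap`) or `NULL`,
#'   and `positioned` flag.
#' @export
scan_tata_positioned <- function(upstream_seq, model) {
  U <- nchar(upstream_seq)
  L <- model$tata$length
  w <- model$tata_offset_window
  need <- w[2] + L
  if (U < need)
    stop(sprintf("upstream context too short for positioned TATA scan: %d nt given, %d required",
                 U, need), call. = FALSE)
  sc <- score_all_windows(model$tata, upstream_seq)
  starts <- as.integer(names(sc))
  gaps <- U - (starts + L - 1L)
  ok <- sc >= model$tata_threshold
  if (!any(ok)) return(list(hit = NULL, positioned = FALSE))
  in_win <- ok & gaps >= w[1] & gaps <= w[2]
  pool <- if (any(in_win)) which(in_win) else which(ok)
  i <- pool[which.max(sc[pool])]
  list(hit = list(start = starts[i], score = unname(sc[i]), length = L,
                  gap = gaps[i]),
       positioned = any(in_win))
}

#' Call a poly-T pol III terminator downstream of a locus
#'
#' Finds the first run of at least `min_run` consecutive `T` on the locus
#' sense strand, starting from the base immediately after the locus 3' end.
#'
#' @param downstream_seq sense-strand DNA beginning at locus 3' end + 1.
#' @param min_run minimum run length (default 4).
#' @param proximal_window a run starting at most this many nt downstream is
#'   flagged proximal (default 30).
#' @return list with `run_start` (nt downstream of the 3' end; 0 =
#'   immediately adjacent), `run_length`, `proximal`; or `NULL` when no
#'   qualifying run exists.
#' @export
scan_polyT <- function(downstream_seq, min_run = 4L, proximal_window = 30L) {
  if (min_run < 1L) stop("'min_run' must be >= 1", call. = FALSE)
  if (!nzchar(downstream_seq)) return(NULL)
  downstream_seq <- check_dna(downstream_seq, "downstream_seq")
  m <- regexpr(paste0("T{", min_run, ",}"), downstream_seq)
  if (m < 0L) return(NULL)
  run_start <- as.integer(m) - 1L
  list(run_start = run_start,
       run_length = attr(m, "match.length"),
       proximal = run_start <= proximal_window)
}

#' Scan a locus for internal pol III promoter elements (A-box / B-box)
#'
#' tRNA-class pol III genes carry gene-internal recognition sequences; this
#' scan reports whether the locus contains an A-box match followed (wholly
#' downstream) by a B-box match.
#'
#' @param locus_seq sense-strand DNA of the locus.
#' @param abox,bbox IUPAC motifs (defaults from [polr3_defaults()]).
#' @return list with `found` flag and, when found, `abox_start` and
#'   `bbox_start` (1-based) of the first qualifying pair.
#' @export
scan_internal_promoter <- function(locus_seq,
                                   abox = polr3_defaults()$abox,
                                   bbox = polr3_defaults()$bbox) {
  a <- match_iupac(abox, locus_seq)
  b <- match_iupac(bbox, locus_seq)
  la <- nchar(abox)
  for (s in a) {
    after <- b[b > s + la - 1L]
    if (length(after))
      return(list(found = TRUE, abox_start = s, bbox_start = min(after)))
  }
  list(found = FALSE, abox_start = NA_integer_, bbox_start = NA_integer_)
}

#' Assemble per-locus evidence into a pol III verdict
#'
#' The verdict is `polIII_positive` if and only if a PSE hit is present and
#' the TATA hit is appropriately positioned; the terminator call and the
#' internal-promoter flag are recorded as supporting evidence only (poly-T
#' runs occur at variable positions even in signal-free genes and are not
#' by themselves diagnostic).
#'
#' @param pse_hit PSE hit (list or `NULL`), e.g. from [scan_pse()].
#' @param tata list as returned by [scan_tata_positioned()].
#' @param terminator terminator call (list or `NULL`) from [scan_polyT()].
#' @param internal internal-promoter call from [scan_internal_promoter()].
#' @return object of class `"polIII_status"`: list with the evidence fields
#'   and `verdict` (`"polIII_positive"` or `"polIII_negative"`).
#' @export
assemble_polIII_evidence <- function(pse_hit, tata, terminator = NULL,
                                     internal = list(found = FALSE)) {
  verdict <- if (!is.null(pse_hit) && isTRUE(tata$positioned))
    "polIII_positive" else "polIII_negative"
  structure(
    list(pse_hit = pse_hit, tata_hit = tata$hit,
         tata_positioned = isTRUE(tata$positioned),
         terminator = terminator,
         internal_promoter = isTRUE(internal$found),
         verdict = verdict),
    class = "polIII_status"
  )
}

#' @export
print.polIII_status <- function(x, ...) {
  cat("pol III promoter evidence\n")
  cat("  PSE hit          :",
      if (is.null(x$pse_hit)) "absent" else
        sprintf("%.2f bits, %d nt upstream", x$pse_hit$score,
                x$pse_hit$dist %||% x$pse_hit$start), "\n")
  cat("  TATA hit         :",
      if (is.null(x$tata_hit)) "absent" else
        sprintf("%.2f bits, gap %d nt%s", x$tata_hit$score, x$tata_hit$gap,
                if (x$tata_positioned) " (positioned)" else ""), "\n")
  cat("  poly-T terminator:",
      if (is.null(x$terminator)) "absent" else
        sprintf("run of %d T at +%d%s", x$terminator$run_length,
                x$terminator$run_start,
                if (x$terminator$proximal) " (proximal)" else ""), "\n")
  cat("  internal A/B box :", if (x$internal_promoter) "present" else "absent", "\n")
  cat("  verdict          :", x$verdict, "\n")
  invisible(x)
}

## Extract the sense-strand upstream / locus / downstream sequences of one
## locus, honouring strand (for a minus-strand locus, "upstream" lies at
## higher genomic coordinates and is reverse-complemented).
locus_sequences <- function(genome, chrom, start, end, strand,
                            up_len, down_len) {
  if (!chrom %in% names(genome))
    stop("locus on unknown sequence id: ", chrom, call. = FALSE)
  chr <- genome[[chrom]]
  n <- length(chr)
  getseq <- function(s, e) {
    if (s > e) return("")
    as.character(Biostrings::subseq(chr, max(1L, s), min(n, e)))
  }
  if (strand == "-") {
    up <- revcomp(getseq(end + 1L, end + up_len))
    down <- revcomp(getseq(start - down_len, start - 1L))
    locus <- revcomp(getseq(start, end))
  } else {
    up <- getseq(start - up_len, start - 1L)
    down <- getseq(end + 1L, end + down_len)
    locus <- getseq(start, end)
  }
  list(upstream = up, locus = locus, downstream = down)
}

#' Scan candidate loci for pol III type-3 promoter architecture
#'
#' For each locus, extracts the sense-strand upstream context (length = the
#' model's maximal PSE search distance), the locus sequence, and
#' `downstream_scan` nt of downstream context, runs [scan_pse()],
#' [scan_tata_positioned()], [scan_polyT()] and [scan_internal_promoter()],
#' and assembles the verdict with [assemble_polIII_evidence()]. Minus-strand
#' loci are scanned on the reverse complement, so results are
#' strand-symmetric by construction.
#'
#' @param genome `DNAStringSet` or path to a genome FASTA.
#' @param loci `GRanges` with a `name` column, or path to a BED6 file.
#' @param model a [`promoter_model`][promoter_model()].
#' @param min_run,proximal_window passed to [scan_polyT()].
#' @param downstream_scan nt of downstream sequence searched for the
#'   terminator (default 60).
#' @param abox,bbox internal-promoter motifs.
#' @return `data.frame` with one row per locus: `locus_id`, `pse_score`,
#'   `pse_dist`, `tata_score`, `tata_gap`, `tata_positioned`, `polyT_start`,
#'   `polyT_len`, `proximal`, `internal_promoter`, `verdict`. Absent hits
#'   are `NA`.
#' @export
scan_loci <- function(genome, loci, model,
                      min_run = 4L, proximal_window = 30L,
                      downstream_scan = 60L,
                      abox = polr3_defaults()$abox,
                      bbox = polr3_defaults()$bbox) {
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(loci)) loci <- read_loci_bed(loci)
  stopifnot(inherits(model, "promoter_model"))
  up_len <- model$pse_search_window[2]
  ids <- loci$name %||% as.character(seq_along(loci))

  rows <- lapply(seq_along(loci), function(i) {
    sq <- locus_sequences(genome, as.character(seqnames(loci)[i]),
                          start(loci)[i], end(loci)[i],
                          as.character(strand(loci)[i]),
                          up_len, downstream_scan)
    pse <- scan_pse(sq$upstream, model)
    tata <- scan_tata_positioned(sq$upstream, model)
    term <- scan_polyT(sq$downstream, min_run, proximal_window)
    internal <- scan_internal_promoter(sq$locus, abox, bbox)
    st <- assemble_polIII_evidence(pse, tata, term, internal)
    data.frame(
      locus_id = ids[i],
      pse_score = if (is.null(pse)) NA_real_ else pse$score,
      pse_dist = if (is.null(pse)) NA_integer_ else pse$dist,
      tata_score = if (is.null(tata$hit)) NA_real_ else tata$hit$score,
      tata_gap = if (is.null(tata$hit)) NA_integer_ else tata$hit$gap,
      tata_positioned = st$tata_positioned,
      polyT_start = if (is.null(term)) NA_integer_ else term$run_start,
      polyT_len = if (is.null(term)) NA_integer_ else term$run_length,
      proximal = if (is.null(term)) NA else term$proximal,
      internal_promoter = st$internal_promoter,
      verdict = st$verdict,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
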