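#' Build a position weight matrix from aligned sequences
#'
#' Tabulates per-position base frequencies over an alignment of equal-length
#' DNA strings and converts them to smoothed probabilities,
#' `(count + pseudocount) / (n_seqs + 4 * pseudocount)`. `N` characters
#' contribute 1/4 of a count to each base, so an assembly gap neither favours
#' nor penalises any base.
#'
#' @param seqs character vector (or `DNAStringSet`) of equal-length DNA
#'   strings over `{A,C,G,T,N}`; at least one sequence.
#' @param pseudocount non-negative smoothing constant added to every cell
#'   (default 0.25).
#' @param background base composition of the null model, probabilities over
#'   A,C,G,T summing to 1 (default uniform).
#' @return an object of class `"pwm"`: a list with elements `probs` (4 x L
#'   matrix, rows A,C,G,T; columns sum to 1), `background`, `pseudocount`,
#'   `nseq` and `length`.
#' @examples
#' build_pwm(c("TATA", "TACA", "TATA", "AATA"), pseudocount = 0.25)
#' @seealso [score_window()], [consensus_iupac()], [calibrate_threshold()]
#' @export
build_pwm <- function(seqs, pseudocount = 0.25,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!length(seqs)) stop("at least one training sequence is required",
                          call. = FALSE)
  seqs <- vapply(seqs, check_dna, character(1), arg = "seqs", USE.NAMES = FALSE)
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("all sequences must have equal length (ragged input)", call. = FALSE)
  if (L < 1L) stop("sequences must be non-empty", call. = FALSE)
  if (pseudocount < 0) stop("'pseudocount' must be >= 0", call. = FALSE)
  background <- check_background(background)

  counts <- matrix(0, nrow = 4L, ncol = L, dimnames = list(.BASES, NULL))
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (j in seq_len(L)) {
    col <- mat[, j]
    nn <- sum(col == "N")
    for (b in .BASES)
      counts[b, j] <- sum(col == b) + nn / 4
  }
  probs <- (counts + pseudocount) / (length(seqs) + 4 * pseudocount)
  structure(
    list(probs = probs, background = background,
         pseudocount = pseudocount, nseq = length(seqs), length = L),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("Position weight matrix: %d positions, %d sequence(s), pseudocount %g\n",
              x$length, x$nseq, x$pseudocount))
  cat("Consensus:", consensus_iupac(x), "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' @export
plot.pwm <- function(x, ...) {
  ic <- apply(x$probs, 2L, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
  graphics::barplot(ic, names.arg = seq_along(ic),
                    xlab = "position", ylab = "information (bits)",
                    main = consensus_iupac(x), ...)
  invisible(x)
}

#' Sample sequences from a position weight matrix
#'
#' Draws `nsim` independent sequences, each position sampled from the
#' matrix's per-position base probabilities.
#'
#' @param object a [`pwm`][build_pwm()].
#' @param nsim number of sequences.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return character vector of length `nsim`.
#' @export
simulate.pwm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(nsim), function(i) {
    paste(vapply(seq_len(object$length), function(j)
      sample(.BASES, 1L, prob = object$probs[, j]), character(1)),
      collapse = "")
  }, character(1))
}

#' Collapse a PWM to a degenerate IUPAC consensus
#'
#' At each position, every base whose probability is at least
#' `inclusion_fraction` times the maximum probability at that position is
#' retained, and the retained set is written as a single IUPAC code.
#'
#' @param pwm a [`pwm`][build_pwm()].
#' @param inclusion_fraction in (0, 1]; 1 keeps only bases tied with the
#'   maximum, smaller values admit near-maximal bases (default 0.5).
#' @return an IUPAC string of length `pwm$length`.
#' @export
consensus_iupac <- function(pwm, inclusion_fraction = 0.5) {
  stopifnot(inherits(pwm, "pwm"))
  if (!(inclusion_fraction > 0 && inclusion_fraction <= 1))
    stop("'inclusion_fraction' must be in (0, 1]", call. = FALSE)
  rev_map <- setNames(names(.IUPAC), vapply(.IUPAC, function(x)
    paste(sort(strsplit(x, "")[[1]]), collapse = ""), character(1)))
  codes <- vapply(seq_len(pwm$length), function(j) {
    p <- pwm$probs[, j]
    keep <- .BASES[p >= inclusion_fraction * max(p)]
    rev_map[[paste(sort(keep), collapse = "")]]
  }, character(1))
  paste(codes, collapse = "")
}

#' Score one sequence window against a PWM
#'
#' Log-odds score in bits: the sum over positions of
#' `log2(probs[base, pos] / background[base])`. An `N` in the window
#' contributes 0 bits at its position.
#'
#' @param pwm a [`pwm`][build_pwm()].
#' @param seq DNA string.
#' @param start 1-based offset of the window's first base in `seq`.
#' @return score in bits (single numeric).
#' @export
score_window <- function(pwm, seq, start = 1L) {
  stopifnot(inherits(pwm, "pwm"))
  seq <- check_dna(seq)
  L <- pwm$length
  if (start < 1L || start + L - 1L > nchar(seq))
    stop(sprintf("window [%d, %d] out of range for sequence of length %d",
                 start, start + L - 1L, nchar(seq)), call. = FALSE)
  chars <- strsplit(substr(seq, start, start + L - 1L), "")[[1]]
  s <- 0
  for (j in seq_len(L)) {
    b <- chars[j]
    if (b != "N")
      s <- s + log2(pwm$probs[b, j] / pwm$background[b])
  }
  unname(s)
}

## Scores for every window start in `starts` (default: all valid starts).
## Returns a numeric vector named by start.
score_all_windows <- function(pwm, seq, starts = NULL) {
  seq <- check_dna(seq)
  n <- nchar(seq) - pwm$length + 1L
  if (n < 1L) return(setNames(numeric(0), character(0)))
  if (is.null(starts)) starts <- seq_len(n)
  setNames(vapply(starts, function(s) score_window(pwm, seq, s), numeric(1)),
           starts)
}

#' Calibrate a score threshold from training sequences
#'
#' For each training sequence, the best window score under the PWM is
#' computed; the threshold is the minimum of these best scores minus
#' `margin`, so that at margin 0 every training sequence passes its own
#' model.
#'
#' @param pwm a [`pwm`][build_pwm()].
#' @param training_seqs character vector of DNA strings, each at least as
#'   long as the PWM.
#' @param margin non-negative slack in bits subtracted from the minimum
#'   (default 0).
#' @return threshold in bits.
#' @export
calibrate_threshold <- function(pwm, training_seqs, margin = 0) {
  if (methods::is(training_seqs, "DNAStringSet"))
    training_seqs <- as.character(training_seqs)
  if (!length(training_seqs))
    stop("at least one training sequence is required", call. = FALSE)
  short <- nchar(training_seqs) < pwm$length
  if (any(short))
    stop(sprintf("%d training sequence(s) shorter than the PWM (%d nt)",
                 sum(short), pwm$length), call. = FALSE)
  best <- vapply(training_seqs, function(s) max(score_all_windows(pwm, s)),
                 numeric(1))
  min(best) - margin
}
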