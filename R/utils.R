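## IUPAC nucleotide codes and small sequence helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

.IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

check_iupac <- function(motif, arg = "motif") {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) < 1L)
    stop(sprintf("'%s' must be a single non-empty string", arg), call. = FALSE)
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad))
    stop(sprintf("invalid IUPAC symbol(s) in %s: %s", arg,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  paste(chars, collapse = "")
}

check_dna <- function(seq, arg = "seq", allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L)
    stop(sprintf("'%s' must be a single string", arg), call. = FALSE)
  seq <- toupper(seq)
  alphabet <- if (allow_n) c(.BASES, "N") else .BASES
  chars <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(chars, alphabet)
  if (length(bad))
    stop(sprintf("'%s' contains non-DNA characters: %s", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  seq
}

iupac_to_regex <- function(motif) {
  chars <- strsplit(check_iupac(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    ex <- .IUPAC[[ch]]
    if (nchar(ex) == 1L) ex else
      paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## i.i.d. background sequence at a given GC fraction (uses the current RNG
## stream; callers are responsible for seeding).
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

## Per-site substitution at the given rate; a mutated site is replaced by
## one of the three other bases uniformly.
mutate_dna <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

## Break every run of >= min_run consecutive T so a region carries no
## spurious pol III terminator signal.
break_polyT <- function(seq, min_run = 4L) {
  if (!nzchar(seq)) return(seq)
  pat <- paste0("T{", min_run, ",}")
  while (grepl(pat, seq)) {
    m <- regexpr(pat, seq)
    at <- as.integer(m) + min_run - 1L
    substr(seq, at, at) <- "C"
  }
  seq
}

## Background probabilities: named numeric over A,C,G,T summing to 1.
check_background <- function(background) {
  if (is.null(names(background))) names(background) <- .BASES
  background <- background[.BASES]
  if (any(is.na(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stop("'background' must be positive probabilities over A,C,G,T summing to 1",
         call. = FALSE)
  background
}

`%||%` <- function(a, b) if (is.null(a)) b else a
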