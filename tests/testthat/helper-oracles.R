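# Independent brute-force oracles shared by unit and acceptance tests.
# These deliberately use naive per-position / per-base computation and no
# package internals beyond the public API under test.

# all match starts of an IUPAC motif by regex expansion at every offset
iupac_oracle <- function(motif, s) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  re <- paste(map[strsplit(motif, "")[[1]]], collapse = "")
  n <- nchar(motif)
  which(vapply(seq_len(max(0, nchar(s) - n + 1)), function(i)
    grepl(paste0("^", re, "$"), substr(s, i, i + n - 1)), logical(1)))
}

# first run of >= k consecutive T, by character loop
polyT_oracle <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  run <- 0
  for (i in seq_along(ch)) {
    run <- if (ch[i] == "T") run + 1 else 0
    if (run == k) {
      j <- i + 1
      while (j <= length(ch) && ch[j] == "T") j <- j + 1
      return(c(start = i - k, len = j - (i - k + 1)))
    }
  }
  NULL
}

# placement of a locus against simple single-transcript gene models
placement_oracle <- function(locus_start, locus_end, genes) {
  for (g in genes) {
    if (locus_end < g$start || locus_start > g$end) next
    in_exon <- any(vapply(seq_len(nrow(g$exons)), function(e)
      locus_end >= g$exons[e, 1] && locus_start <= g$exons[e, 2],
      logical(1)))
    if (in_exon) return("overlapping_exon")
    for (e in seq_len(nrow(g$exons) - 1)) {
      if (locus_start >= g$exons[e, 2] + 1 &&
          locus_end <= g$exons[e + 1, 1] - 1) return("intronic")
    }
    return("overlapping_exon")
  }
  "intergenic"
}

# a random non-overlapping annotation written as GFF3; returns the path
# and the gene structures for the oracle (uses the current RNG stream)
random_annotation <- function(n_genes = 4) {
  cursor <- 100
  genes <- list()
  lines <- character(0)
  for (g in seq_len(n_genes)) {
    n_exons <- sample(2:4, 1)
    ex <- matrix(0, n_exons, 2)
    pos <- cursor
    for (e in seq_len(n_exons)) {
      ex[e, ] <- c(pos, pos + sample(50:150, 1))
      pos <- ex[e, 2] + sample(100:300, 1) + 1
    }
    strand <- sample(c("+", "-"), 1)
    gid <- paste0("g", g)
    lines <- c(lines,
      sprintf("chrN\tt\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              ex[1, 1], ex[n_exons, 2], strand, gid),
      sprintf("chrN\tt\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s_t1;Parent=%s",
              ex[1, 1], ex[n_exons, 2], strand, gid, gid),
      vapply(seq_len(n_exons), function(e)
        sprintf("chrN\tt\texon\t%d\t%d\t.\t%s\t.\tParent=%s_t1",
                ex[e, 1], ex[e, 2], strand, gid), character(1)))
    genes[[g]] <- list(start = ex[1, 1], end = ex[n_exons, 2], exons = ex)
    cursor <- ex[n_exons, 2] + sample(200:400, 1)
  }
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  list(path = path, genes = genes, span = cursor)
}
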