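## Seeded synthetic species: genome, annotation, candidate loci, promoter
## training set, read counts and truth labels. Two planted architectures
## mirror the two gene classes the pipeline must tell apart: signal-free
## loci embedded in host-gene introns, and intergenic loci carrying a full
## pol III type-3 promoter cassette (PSE, TATA at a sampled gap in
## 21-27 nt, 3' poly-T run of 4-5 nt).

#' Configuration for a synthetic species
#'
#' Validates and fills a generation config. Defaults describe a compact
#' but structurally realistic species: ~30 kb genome, a few multi-exon
#' host genes with introns long enough to harbour a ~300 nt ncRNA, and a
#' U6/7SK-like training set sharing the species promoter consensus with
#' per-site substitution noise. Noise perturbs the training promoters
#' (and hence the fitted model and its calibrated thresholds); the
#' promoter instances planted at independent loci are exact consensus, so
#' every recorded signal position can be re-found by literal string
#' matching in the emitted genome.
#'
#' @param genome_length total chromosome length in bp.
#' @param gc_content background GC fraction in `[0, 1]`.
#' @param n_host_genes number of host (recipient) genes.
#' @param exons_per_gene exons per gene (>= 2, so every gene has introns).
#' @param n_embedded_loci signal-free loci planted inside host introns.
#' @param n_independent_loci intergenic loci planted with the full pol III
#'   cassette.
#' @param tata_offset_range inclusive range of the planted TATA gap
#'   (default `c(21, 27)`).
#' @param polyT_run_range inclusive range of the planted terminator run
#'   length (default `c(4, 5)`).
#' @param promoter_noise per-site substitution probability in `[0, 1)`
#'   applied to every planted PSE/TATA instance.
#' @param n_training_promoters size of the U6/7SK-like training set.
#' @param seed integer seed; the run is byte-deterministic given the seed.
#' @param locus_length ncRNA locus length in bp (default 300).
#' @param exon_length_range,intron_length_range sampled feature sizes.
#' @param pse_consensus,tata_consensus planted consensus strings (defaults
#'   from [polr3_defaults()]).
#' @param pse_dist_range range of the planted PSE distance (PSE first base
#'   to locus first base; default `c(45, 80)`).
#' @param signatures named IUPAC motifs planted inside every locus so
#'   candidates validate as bona fide RPR/MRP-like RNAs.
#' @param max_retries bounded retries for non-overlapping placement before
#'   a hard error (default 100).
#' @return validated config list of class `"species_config"`.
#' @export
species_config <- function(genome_length = 30000L, gc_content = 0.45,
                           n_host_genes = 3L, exons_per_gene = 3L,
                           n_embedded_loci = 2L, n_independent_loci = 2L,
                           tata_offset_range = c(21L, 27L),
                           polyT_run_range = c(4L, 5L),
                           promoter_noise = 0,
                           n_training_promoters = 12L,
                           seed = 1L,
                           locus_length = 300L,
                           exon_length_range = c(150L, 300L),
                           intron_length_range = c(500L, 800L),
                           pse_consensus = polr3_defaults()$pse_consensus,
                           tata_consensus = polr3_defaults()$tata_consensus,
                           pse_dist_range = c(45L, 80L),
                           signatures = polr3_defaults()$signatures,
                           max_retries = 100L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_content = gc_content,
              n_host_genes = as.integer(n_host_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_embedded_loci = as.integer(n_embedded_loci),
              n_independent_loci = as.integer(n_independent_loci),
              tata_offset_range = as.integer(tata_offset_range),
              polyT_run_range = as.integer(polyT_run_range),
              promoter_noise = promoter_noise,
              n_training_promoters = as.integer(n_training_promoters),
              seed = as.integer(seed),
              locus_length = as.integer(locus_length),
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              pse_consensus = check_dna(pse_consensus, "pse_consensus"),
              tata_consensus = check_dna(tata_consensus, "tata_consensus"),
              pse_dist_range = as.integer(pse_dist_range),
              signatures = signatures,
              max_retries = as.integer(max_retries))
  counts <- c("genome_length", "n_host_genes", "n_embedded_loci",
              "n_independent_loci", "n_training_promoters", "locus_length")
  for (f in counts)
    if (cfg[[f]] < 0L) stop("'", f, "' must be >= 0", call. = FALSE)
  if (cfg$exons_per_gene < 2L)
    stop("'exons_per_gene' must be >= 2", call. = FALSE)
  if (cfg$gc_content < 0 || cfg$gc_content > 1)
    stop("'gc_content' must be in [0, 1]", call. = FALSE)
  if (cfg$promoter_noise < 0 || cfg$promoter_noise >= 1)
    stop("'promoter_noise' must be in [0, 1)", call. = FALSE)
  for (f in c("tata_offset_range", "polyT_run_range", "pse_dist_range",
              "exon_length_range", "intron_length_range"))
    if (length(cfg[[f]]) != 2L || cfg[[f]][1] > cfg[[f]][2])
      stop("'", f, "' must be a non-empty inclusive pair", call. = FALSE)
  if (cfg$n_embedded_loci > 0L &&
      (cfg$n_host_genes < 1L))
    stop("embedded loci require at least one host gene", call. = FALSE)
  class(cfg) <- "species_config"
  cfg
}

## Inclusive-range integer sampler robust to length-1 ranges (sample(5, 1)
## would otherwise mean sample(1:5, 1)).
sample_range <- function(rng, n = 1L) {
  v <- seq.int(rng[1], rng[2])
  if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
}

## One concrete expansion of an IUPAC motif (each position sampled
## uniformly from its allowed bases).
expand_iupac <- function(motif) {
  chars <- strsplit(check_iupac(motif), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- strsplit(.IUPAC[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

## ncRNA locus sequence: background with concrete signature-motif
## instances planted at spread-out positions.
make_locus_seq <- function(len, gc, signatures) {
  s <- random_dna(len, gc)
  k <- length(signatures)
  for (i in seq_along(signatures)) {
    inst <- expand_iupac(signatures[[i]])
    at <- max(1L, round(len * i / (k + 1)))
    if (at + nchar(inst) - 1L > len) at <- len - nchar(inst) + 1L
    substr(s, at, at + nchar(inst) - 1L) <- inst
  }
  s
}

## Full pol III cassette on the locus sense strand. Returns the string
## plus the planted coordinates (1-based within the cassette).
make_polIII_cassette <- function(cfg) {
  P <- nchar(cfg$pse_consensus)
  g <- sample_range(cfg$tata_offset_range)
  d_min <- max(cfg$pse_dist_range[1], g + 6L + P)
  if (d_min > cfg$pse_dist_range[2])
    stop("pse_dist_range too narrow for the sampled TATA gap", call. = FALSE)
  d <- sample_range(c(d_min, cfg$pse_dist_range[2]))
  r <- sample_range(cfg$polyT_run_range)
  dt <- sample_range(c(0L, max(0L, 30L - r)))
  L <- cfg$locus_length

  ## planted signals are exact consensus instances, so the truth table's
  ## positions stay literally re-scannable; promoter_noise perturbs the
  ## training promoters (and hence the fitted model), not the loci
  pse <- cfg$pse_consensus
  tata <- cfg$tata_consensus
  filler <- random_dna(d - g - 6L - P, cfg$gc_content)
  gapseq <- random_dna(g, cfg$gc_content)
  locus <- make_locus_seq(L, cfg$gc_content, cfg$signatures)
  dtseq <- break_polyT(random_dna(dt, cfg$gc_content),
                       cfg$polyT_run_range[1])
  if (nzchar(dtseq) && substr(dtseq, dt, dt) == "T")
    substr(dtseq, dt, dt) <- "C"
  tail <- random_dna(10L, cfg$gc_content)
  if (substr(tail, 1L, 1L) == "T") substr(tail, 1L, 1L) <- "G"

  seq <- paste0(pse, filler, tata, gapseq, locus, dtseq,
                strrep("T", r), tail)
  list(seq = seq,
       locus_start = d + 1L, locus_end = d + L,
       pse_dist = d, tata_offset = g, terminator_start = dt,
       run_length = r)
}

## Place k non-overlapping loci of length L inside an intron of length
## `ilen`, with a margin at both ends; bounded retries, then a hard error.
place_in_intron <- function(k, L, ilen, gene_id, max_retries,
                            margin = 10L) {
  if (ilen < k * (L + margin) + margin)
    stop(sprintf("intron of gene %s too short (%d bp) for %d embedded locus/loci of %d bp",
                 gene_id, ilen, k, L), call. = FALSE)
  for (try in seq_len(max_retries)) {
    starts <- sort(sample(seq.int(margin + 1L, ilen - L - margin + 1L), k))
    if (k == 1L || all(diff(starts) >= L + 1L)) return(starts)
  }
  stop(sprintf("could not place %d embedded locus/loci in an intron of gene %s after %d retries",
               k, gene_id, max_retries), call. = FALSE)
}

#' Generate a synthetic species
#'
#' Emits a seeded, byte-deterministic synthetic species: genome FASTA,
#' GFF3 gene annotation (gene/mRNA/exon), BED6 candidate loci, a FASTA of
#' U6/7SK-like training promoters, and a truth table recording every
#' planted label and signal position.
#'
#' Embedded loci are placed fully inside one intron of one host gene and
#' carry no promoter signals; independent loci are intergenic and carry a
#' PSE at a sampled upstream distance, a TATA box at a sampled gap within
#' `tata_offset_range`, and a proximal poly-T run within `polyT_run_range`.
#' Sequence between the locus 3' end and the planted terminator is
#' scrubbed of spurious T-runs so the planted run is the first terminator
#' downstream.
#'
#' @param config a [species_config()].
#' @param dir output directory (created if needed).
#' @param species_id label used in sequence, gene and locus ids.
#' @return (invisibly) list with `paths` (genome, annotation, candidates,
#'   promoters, truth), `truth` (`data.frame`), `species_id` and `config`.
#' @export
generate_species <- function(config, dir, species_id = "sp1") {
  stopifnot(inherits(config, "species_config"))
  cfg <- config
  set.seed(cfg$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chrom <- paste0(species_id, "_chr1")
  n_intr <- cfg$exons_per_gene - 1L

  ## ---- host gene geometry, then capacity-aware embedding ----
  margin <- 10L
  exon_lens_all <- lapply(seq_len(cfg$n_host_genes), function(g)
    sample_range(cfg$exon_length_range, cfg$exons_per_gene))
  intron_lens_all <- lapply(seq_len(cfg$n_host_genes), function(g)
    sample_range(cfg$intron_length_range, n_intr))
  gstrands <- vapply(seq_len(cfg$n_host_genes), function(g)
    sample(c("+", "-"), 1L), character(1))

  ## each intron offers floor((len - margin) / (locus + margin)) slots;
  ## embedded loci are assigned by sampling slots so no intron is
  ## overfilled when capacity exists elsewhere
  embed_assign <- data.frame(gene = integer(0), intron = integer(0))
  if (cfg$n_embedded_loci > 0L) {
    pool <- do.call(rbind, lapply(seq_len(cfg$n_host_genes), function(g) {
      do.call(rbind, lapply(seq_len(n_intr), function(j) {
        cap <- max(0L, (intron_lens_all[[g]][j] - margin) %/%
                     (cfg$locus_length + margin))
        if (cap > 0L) data.frame(gene = rep(g, cap), intron = rep(j, cap))
        else NULL
      }))
    }))
    if (is.null(pool) || nrow(pool) < cfg$n_embedded_loci) {
      widest <- which.max(vapply(intron_lens_all, max, numeric(1)))
      stop(sprintf("intron of gene %s_g%d too short (%d bp) for %d embedded locus/loci of %d bp",
                   species_id, widest, max(intron_lens_all[[widest]]),
                   cfg$n_embedded_loci, cfg$locus_length), call. = FALSE)
    }
    pick <- pool[sample.int(nrow(pool), cfg$n_embedded_loci), , drop = FALSE]
    embed_assign <- pick[order(pick$gene, pick$intron), , drop = FALSE]
  }

  genes <- vector("list", cfg$n_host_genes)
  emb_i <- 0L
  for (g in seq_len(cfg$n_host_genes)) {
    gene_id <- sprintf("%s_g%d", species_id, g)
    gstrand <- gstrands[g]
    exon_lens <- exon_lens_all[[g]]
    intron_lens <- intron_lens_all[[g]]
    pieces <- character(0)
    exon_rel <- matrix(0L, nrow = cfg$exons_per_gene, ncol = 2L)
    cur <- 0L
    gene_loci <- list()
    for (e in seq_len(cfg$exons_per_gene)) {
      pieces <- c(pieces, random_dna(exon_lens[e], cfg$gc_content))
      exon_rel[e, ] <- c(cur + 1L, cur + exon_lens[e])
      cur <- cur + exon_lens[e]
      if (e <= n_intr) {
        j <- e  # genomic intron index, left to right
        here <- which(embed_assign$gene == g & embed_assign$intron == j)
        iseq <- random_dna(intron_lens[j], cfg$gc_content)
        if (length(here)) {
          starts <- place_in_intron(length(here), cfg$locus_length,
                                    intron_lens[j], gene_id,
                                    cfg$max_retries)
          for (idx in seq_along(here)) {
            emb_i <- emb_i + 1L
            lstrand <- if (stats::runif(1) < 0.8) gstrand else
              setdiff(c("+", "-"), gstrand)
            lseq <- make_locus_seq(cfg$locus_length, cfg$gc_content,
                                   cfg$signatures)
            ins <- if (lstrand == "+") lseq else revcomp(lseq)
            substr(iseq, starts[idx],
                   starts[idx] + cfg$locus_length - 1L) <- ins
            ordinal <- if (gstrand == "+") j else n_intr - j + 1L
            gene_loci[[length(gene_loci) + 1L]] <- list(
              rel_start = cur + starts[idx],
              rel_end = cur + starts[idx] + cfg$locus_length - 1L,
              strand = lstrand, gene_id = gene_id,
              intron_ordinal = ordinal, emb_index = emb_i)
          }
        }
        pieces <- c(pieces, iseq)
        cur <- cur + intron_lens[j]
      }
    }
    genes[[g]] <- list(gene_id = gene_id, strand = gstrand,
                       seq = paste(pieces, collapse = ""),
                       exon_rel = exon_rel, loci = gene_loci)
  }

  ## ---- independent (intergenic) pol III loci ----
  independents <- lapply(seq_len(cfg$n_independent_loci), function(i) {
    lstrand <- sample(c("+", "-"), 1L)
    cas <- make_polIII_cassette(cfg)
    c(cas, list(strand = lstrand))
  })

  ## ---- genome layout: shuffled elements separated by spacers ----
  elements <- c(
    lapply(seq_along(genes), function(g) list(kind = "gene", idx = g,
                                              len = nchar(genes[[g]]$seq))),
    lapply(seq_along(independents), function(i)
      list(kind = "independent", idx = i,
           len = nchar(independents[[i]]$seq)))
  )
  if (length(elements) > 1L) elements <- elements[sample(length(elements))]
  min_spacer <- 150L
  n_sp <- length(elements) + 1L
  used <- sum(vapply(elements, `[[`, numeric(1), "len"))
  free <- cfg$genome_length - used - min_spacer * n_sp
  if (free < 0L)
    stop(sprintf("genome_length %d too small: elements need %d bp plus %d bp of minimum spacers",
                 cfg$genome_length, used, min_spacer * n_sp), call. = FALSE)
  extra <- as.vector(stats::rmultinom(1L, free, rep(1, n_sp)))
  spacers <- min_spacer + extra

  parts <- character(0)
  cursor <- 0L
  gene_abs <- integer(length(genes))
  indep_abs <- integer(length(independents))
  for (k in seq_along(elements)) {
    parts <- c(parts, random_dna(spacers[k], cfg$gc_content))
    cursor <- cursor + spacers[k]
    el <- elements[[k]]
    if (el$kind == "gene") {
      gene_abs[el$idx] <- cursor + 1L
      parts <- c(parts, genes[[el$idx]]$seq)
    } else {
      indep_abs[el$idx] <- cursor + 1L
      ind <- independents[[el$idx]]
      parts <- c(parts,
                 if (ind$strand == "+") ind$seq else revcomp(ind$seq))
    }
    cursor <- cursor + el$len
  }
  parts <- c(parts, random_dna(spacers[n_sp], cfg$gc_content))
  genome_seq <- paste(parts, collapse = "")

  ## ---- truth table and candidate loci ----
  truth <- list()
  loci_gr <- list()
  for (g in seq_along(genes)) {
    for (lc in genes[[g]]$loci) {
      id <- sprintf("%s_L%02d", species_id, lc$emb_index)
      s <- gene_abs[g] + lc$rel_start - 1L
      e <- gene_abs[g] + lc$rel_end - 1L
      truth[[length(truth) + 1L]] <- data.frame(
        locus_id = id, species_id = species_id, chrom = chrom,
        start = s, end = e, strand = lc$strand,
        planted_class = "embedded_polII",
        pse_dist = NA_integer_, tata_offset = NA_integer_,
        terminator_start = NA_integer_,
        recipient_gene_id = lc$gene_id,
        intron_ordinal = lc$intron_ordinal,
        stringsAsFactors = FALSE)
      loci_gr[[length(loci_gr) + 1L]] <-
        GRanges(chrom, IRanges(s, e), strand = lc$strand, name = id)
    }
  }
  for (i in seq_along(independents)) {
    ind <- independents[[i]]
    id <- sprintf("%s_L%02d", species_id, cfg$n_embedded_loci + i)
    clen <- nchar(ind$seq)
    if (ind$strand == "+") {
      s <- indep_abs[i] + ind$locus_start - 1L
      e <- indep_abs[i] + ind$locus_end - 1L
    } else {
      s <- indep_abs[i] + (clen - ind$locus_end)
      e <- indep_abs[i] + (clen - ind$locus_start)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      locus_id = id, species_id = species_id, chrom = chrom,
      start = s, end = e, strand = ind$strand,
      planted_class = "independent_polIII",
      pse_dist = ind$pse_dist, tata_offset = ind$tata_offset,
      terminator_start = ind$terminator_start,
      recipient_gene_id = NA_character_,
      intron_ordinal = NA_integer_,
      stringsAsFactors = FALSE)
    loci_gr[[length(loci_gr) + 1L]] <-
      GRanges(chrom, IRanges(s, e), strand = ind$strand, name = id)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    locus_id = character(0), species_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    planted_class = character(0), pse_dist = integer(0),
    tata_offset = integer(0), terminator_start = integer(0),
    recipient_gene_id = character(0), intron_ordinal = integer(0),
    stringsAsFactors = FALSE)

  ## ---- training promoters ----
  promoters <- vapply(seq_len(cfg$n_training_promoters), function(i) {
    paste0(random_dna(12L, cfg$gc_content),
           mutate_dna(cfg$pse_consensus, cfg$promoter_noise),
           random_dna(sample_range(c(20L, 28L)), cfg$gc_content),
           mutate_dna(cfg$tata_consensus, cfg$promoter_noise),
           random_dna(30L, cfg$gc_content))
  }, character(1))
  names(promoters) <- ifelse(seq_along(promoters) %% 2L == 1L,
                             sprintf("U6_%d", seq_along(promoters)),
                             sprintf("7SK_%d", seq_along(promoters)))

  ## ---- annotation GRanges ----
  ann <- list()
  for (g in seq_along(genes)) {
    gn <- genes[[g]]
    gs <- gene_abs[g]
    glen <- nchar(gn$seq)
    gene_rng <- GRanges(chrom, IRanges(gs, gs + glen - 1L),
                        strand = gn$strand)
    gene_rng$type <- "gene"; gene_rng$ID <- gn$gene_id
    gene_rng$Parent <- CharacterList(list(character(0)))
    tx <- gene_rng
    tx$type <- "mRNA"; tx$ID <- paste0(gn$gene_id, "_t1")
    tx$Parent <- CharacterList(list(gn$gene_id))
    ex <- GRanges(chrom,
                  IRanges(gs + gn$exon_rel[, 1] - 1L,
                          gs + gn$exon_rel[, 2] - 1L),
                  strand = gn$strand)
    ex$type <- "exon"; ex$ID <- NA_character_
    ex$Parent <- CharacterList(as.list(rep(paste0(gn$gene_id, "_t1"),
                                           length(ex))))
    ann[[g]] <- c(gene_rng, tx, ex)
  }
  ann_gr <- if (length(ann)) do.call(c, ann) else {
    z <- GRanges()
    z$type <- character(0); z$ID <- character(0)
    z$Parent <- CharacterList()
    z
  }

  ## ---- write everything ----
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "genes.gff3"),
    candidates = file.path(dir, "loci.bed"),
    promoters = file.path(dir, "promoters.fa"),
    truth = file.path(dir, "truth.tsv")
  )
  gset <- Biostrings::DNAStringSet(setNames(genome_seq, chrom))
  Biostrings::writeXStringSet(gset, paths$genome)
  write_gff3(ann_gr, paths$annotation, seed = cfg$seed)
  cand <- if (length(loci_gr)) do.call(c, loci_gr) else {
    z <- GRanges(); z$name <- character(0); z
  }
  write_loci_bed(cand, paths$candidates, seed = cfg$seed)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(promoters),
                              paths$promoters)
  write_tsv(truth, paths$truth, seed = cfg$seed)

  invisible(list(paths = paths, truth = truth, species_id = species_id,
                 config = cfg))
}

#' Simulate per-interval read counts
#'
#' Counts are drawn independently per interval as Poisson with mean
#' `density * length` — a stand-in for the unspecified count distribution
#' of tiling/RNA-seq data, chosen as the simplest model with the stated
#' expectation.
#'
#' @param intervals `data.frame` with `interval_id` and `length`, or a
#'   `GRanges` (widths used as lengths, names as ids).
#' @param mean_densities reads per bp, one per interval, all >= 0.
#' @param seed integer seed.
#' @return `data.frame`: `interval_id`, `count`, `length`.
#' @export
simulate_read_counts <- function(intervals, mean_densities, seed = 1L) {
  if (methods::is(intervals, "GRanges"))
    intervals <- data.frame(
      interval_id = intervals$name %||% as.character(seq_along(intervals)),
      length = width(intervals), stringsAsFactors = FALSE)
  if (length(mean_densities) != nrow(intervals))
    stop("'mean_densities' must match the number of intervals", call. = FALSE)
  if (any(mean_densities < 0))
    stop("negative density", call. = FALSE)
  set.seed(seed)
  data.frame(interval_id = intervals$interval_id,
             count = stats::rpois(nrow(intervals),
                                  mean_densities * intervals$length),
             length = intervals$length,
             stringsAsFactors = FALSE)
}

#' Generate a multi-species synthetic panel
#'
#' Builds `n_embedded_species` species whose loci are all intron-embedded
#' and `n_polIII_species` species whose loci are all independent pol III
#' genes, each in its own subdirectory, with a combined truth table and
#' the expected species-level divide.
#'
#' @param dir output directory.
#' @param n_embedded_species,n_polIII_species species counts per side of
#'   the divide (defaults 3 and 3).
#' @param loci_per_species planted loci per species (default 5).
#' @param seed panel seed; species s uses `seed + 97 * s`.
#' @param ... overrides passed to every [species_config()].
#' @return list with `species` (per-species [generate_species()] results),
#'   `truth` (combined), and `expected_groups` (`data.frame` species_id,
#'   group).
#' @export
generate_panel <- function(dir, n_embedded_species = 3L,
                           n_polIII_species = 3L,
                           loci_per_species = 5L, seed = 1L, ...) {
  n <- n_embedded_species + n_polIII_species
  species <- vector("list", n)
  truths <- list()
  groups <- character(n)
  ids <- sprintf("sp%02d", seq_len(n))
  for (s in seq_len(n)) {
    emb <- s <= n_embedded_species
    cfg <- species_config(
      n_embedded_loci = if (emb) loci_per_species else 0L,
      n_independent_loci = if (emb) 0L else loci_per_species,
      seed = seed + 97L * s, ...)
    species[[s]] <- generate_species(cfg, file.path(dir, ids[s]), ids[s])
    truths[[s]] <- species[[s]]$truth
    groups[s] <- if (emb) "embedded" else "polIII"
  }
  names(species) <- ids
  list(species = species, truth = do.call(rbind, truths),
       expected_groups = data.frame(species_id = ids, group = groups,
                                    stringsAsFactors = FALSE))
}
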