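## Placement of candidate loci relative to the gene annotation: intronic
## vs intergenic, recipient gene, intron ordinal, orientation, tandem
## copies. Internal coordinates follow the R/Bioconductor convention
## (1-based, closed intervals, GRanges); BED input is converted at the
## boundary by rtracklayer.

#' Read a GFF3 gene annotation into an internal gene-model object
#'
#' Expects `gene`, `mRNA` and `exon` features linked by `ID`/`Parent`.
#' Introns are derived per transcript as the gaps between consecutive
#' exons; for a multi-transcript gene, context is resolved against the
#' longest transcript.
#'
#' @param path GFF3 file.
#' @return object of class `"gene_annotation"`: list with `genes`
#'   (`GRanges`, `gene_id` column), `tx` (`GRanges`, `tx_id`, `gene_id`),
#'   `exons` and `introns` (`GRangesList` named by `tx_id`; introns in
#'   transcription order), and `main_tx` (named character: chosen
#'   transcript per gene).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  genes <- gr[gr$type == "gene"]
  genes$gene_id <- genes$ID
  tx <- gr[gr$type == "mRNA"]
  tx$tx_id <- tx$ID
  tx$gene_id <- vapply(tx$Parent, `[`, character(1), 1L)
  exons <- gr[gr$type == "exon"]
  exon_parent <- vapply(exons$Parent, `[`, character(1), 1L)
  exons_by_tx <- split(granges(exons), exon_parent)

  introns_by_tx <- lapply(setNames(tx$tx_id, tx$tx_id), function(tid) {
    ex <- sort(exons_by_tx[[tid]])
    if (length(ex) < 2L)
      return(GRanges(seqnames = character(0), ranges = IRanges()))
    intr <- GenomicRanges::setdiff(range(ex), ex)
    str <- as.character(strand(tx)[tx$tx_id == tid])
    if (str == "-") intr <- rev(intr)   # transcription order, 5' to 3'
    intr
  })

  main_tx <- vapply(split(tx, tx$gene_id), function(g) {
    g$tx_id[which.max(width(g))]
  }, character(1))

  structure(list(genes = genes, tx = tx,
                 exons = exons_by_tx, introns = introns_by_tx,
                 main_tx = main_tx),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d gene(s), %d transcript(s) on %d sequence(s)\n",
              length(x$genes), length(x$tx),
              length(unique(as.character(seqnames(x$genes))))))
  invisible(x)
}

## Flanking gene ids for an intergenic locus (ignoring strand); genome
## edges are reported as markers.
flanking_genes <- function(locus, genes) {
  same <- genes[as.character(seqnames(genes)) == as.character(seqnames(locus))]
  left <- same[end(same) < start(locus)]
  right <- same[start(same) > end(locus)]
  list(
    left = if (length(left)) left$gene_id[which.max(end(left))] else "genome_start",
    right = if (length(right)) right$gene_id[which.min(start(right))] else "genome_end"
  )
}

#' Resolve the genomic context of candidate loci
#'
#' Each locus is classified as `intronic` (fully inside one intron of the
#' recipient gene's main transcript), `intergenic` (no gene overlap; both
#' flanking genes reported, genome edges as `genome_start`/`genome_end`),
#' or `overlapping_exon` (any overlap with an exon). Intron ordinals are
#' counted 5' to 3' on the recipient's strand; orientation compares the
#' locus strand with the recipient strand. Gene overlap is assessed
#' ignoring strand, as an embedded ncRNA may lie on either strand of its
#' host.
#'
#' @param loci `GRanges` with a `name` column, or BED6 path.
#' @param annotation a [`gene_annotation`][read_annotation()] (or GFF3
#'   path).
#' @return `data.frame` with one row per locus: `locus_id`, `placement`,
#'   `recipient_gene_id`, `left_gene_id`, `right_gene_id`,
#'   `intron_ordinal`, `n_introns`, `last_intron`, `orientation`
#'   (`same` / `opposite` / `not_applicable`), `containment`
#'   (`full` / `partial`).
#' @export
resolve_context <- function(loci, annotation) {
  if (is.character(loci)) loci <- read_loci_bed(loci)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  stopifnot(inherits(annotation, "gene_annotation"))
  known <- unique(c(as.character(seqnames(annotation$genes)),
                    as.character(seqnames(annotation$tx))))
  ids <- loci$name %||% as.character(seq_along(loci))

  rows <- lapply(seq_along(loci), function(i) {
    locus <- loci[i]
    if (!as.character(seqnames(locus)) %in% known)
      stop("locus '", ids[i], "' on unknown sequence id: ",
           as.character(seqnames(locus)), call. = FALSE)
    out <- data.frame(
      locus_id = ids[i], placement = NA_character_,
      recipient_gene_id = NA_character_,
      left_gene_id = NA_character_, right_gene_id = NA_character_,
      intron_ordinal = NA_integer_, n_introns = NA_integer_,
      last_intron = NA, orientation = "not_applicable",
      containment = NA_character_, stringsAsFactors = FALSE
    )
    ov <- findOverlaps(locus, annotation$genes, ignore.strand = TRUE)
    if (!length(ov)) {
      fl <- flanking_genes(locus, annotation$genes)
      out$placement <- "intergenic"
      out$left_gene_id <- fl$left
      out$right_gene_id <- fl$right
      return(out)
    }
    ## recipient = overlapping gene with the largest overlap
    cand <- annotation$genes[subjectHits(ov)]
    ovw <- width(pintersect(rep(granges(locus), length(cand)), granges(cand)))
    gene <- cand[which.max(ovw)]
    tid <- annotation$main_tx[[gene$gene_id]]
    gstrand <- as.character(strand(gene))
    lstrand <- as.character(strand(locus))
    out$recipient_gene_id <- gene$gene_id
    if (lstrand %in% c("+", "-"))
      out$orientation <- if (lstrand == gstrand) "same" else "opposite"

    exons <- annotation$exons[[tid]]
    introns <- annotation$introns[[tid]]
    if (length(findOverlaps(locus, exons, ignore.strand = TRUE))) {
      out$placement <- "overlapping_exon"
      within_exon <- any(start(exons) <= start(locus) &
                         end(exons) >= end(locus))
      out$containment <- if (within_exon) "full" else "partial"
      return(out)
    }
    holds <- which(start(introns) <= start(locus) & end(introns) >= end(locus))
    if (length(holds) == 1L) {
      out$placement <- "intronic"
      out$intron_ordinal <- holds
      out$n_introns <- length(introns)
      out$last_intron <- holds == length(introns)
      out$containment <- "full"
      return(out)
    }
    ## overlaps the gene body without touching an exon or fitting one
    ## intron (e.g. sticks out past the transcript end of a shorter main
    ## transcript): report as exon-overlapping with partial containment
    out$placement <- "overlapping_exon"
    out$containment <- "partial"
    out
  })
  do.call(rbind, rows)
}

#' Group loci sharing a recipient gene (cohabitation)
#'
#' Loci resolved to the same recipient gene form one group. `same_intron`
#' is `TRUE` when all members lie in one intron; `tandem` additionally
#' requires at least two members, identical orientation, and adjacency (no
#' other candidate locus between consecutive members; within one intron no
#' annotated feature can separate them).
#'
#' @param context `data.frame` from [resolve_context()].
#' @param loci the `GRanges` the context was resolved for (used for
#'   genomic order within a group).
#' @return `data.frame`: `gene_id`, `n_members`, `members`
#'   (comma-separated locus ids in genomic order), `same_intron`, `tandem`.
#'   Singleton groups are included (`tandem = FALSE`).
#' @export
find_cohabitants <- function(context, loci) {
  if (is.character(loci)) loci <- read_loci_bed(loci)
  ids <- loci$name %||% as.character(seq_along(loci))
  intronic <- context[context$placement %in% "intronic", , drop = FALSE]
  if (!nrow(intronic))
    return(data.frame(gene_id = character(0), n_members = integer(0),
                      members = character(0), same_intron = logical(0),
                      tandem = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(split(intronic, intronic$recipient_gene_id), function(g) {
    ord <- order(start(loci)[match(g$locus_id, ids)])
    g <- g[ord, , drop = FALSE]
    same_intron <- length(unique(g$intron_ordinal)) == 1L
    same_orient <- length(unique(g$orientation)) == 1L
    data.frame(gene_id = g$recipient_gene_id[1], n_members = nrow(g),
               members = paste(g$locus_id, collapse = ","),
               same_intron = same_intron,
               tandem = nrow(g) >= 2L && same_intron && same_orient,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
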