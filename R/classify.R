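## The two-group divide: combine the pol III promoter verdict with genomic
## context, per locus and per species.

#' Classify one locus from its pol III verdict and genomic placement
#'
#' A locus with a positive pol III promoter verdict is an independent pol
#' III gene regardless of placement (an intronic locus that carries its own
#' PSE and positioned TATA — the centipede arrangement — is still pol
#' III-driven). A pol III-negative locus fully inside an intron is an
#' embedded, host-dependent gene. Anything else (e.g. pol III-negative and
#' intergenic, as for the body-louse RPR) is left unresolved rather than
#' forced into the divide.
#'
#' @param verdict `"polIII_positive"` or `"polIII_negative"` (vectorised).
#' @param placement `"intronic"`, `"intergenic"` or `"overlapping_exon"`
#'   (vectorised).
#' @return character vector: `"independent_polIII"`, `"embedded_polII"` or
#'   `"unresolved"`.
#' @export
classify_locus <- function(verdict, placement) {
  stopifnot(length(verdict) == length(placement))
  ifelse(verdict == "polIII_positive", "independent_polIII",
         ifelse(placement == "intronic", "embedded_polII", "unresolved"))
}

#' Build the per-locus classification table
#'
#' Joins the promoter-evidence table of [scan_loci()] with the context
#' table of [resolve_context()] on `locus_id` and applies
#' [classify_locus()].
#'
#' @param evidence `data.frame` from [scan_loci()].
#' @param context `data.frame` from [resolve_context()].
#' @param species_id optional species label recycled over rows.
#' @return `data.frame`: `species_id`, `locus_id`, `verdict`, `placement`,
#'   `recipient_gene_id`, `intron_ordinal`, `last_intron`, `orientation`,
#'   `final_class`.
#' @export
classify_loci <- function(evidence, context, species_id = NA_character_) {
  m <- merge(evidence[, c("locus_id", "verdict")],
             context[, c("locus_id", "placement", "recipient_gene_id",
                         "intron_ordinal", "last_intron", "orientation")],
             by = "locus_id", sort = FALSE)
  if (nrow(m) != nrow(evidence))
    stop("evidence and context tables do not cover the same loci",
         call. = FALSE)
  data.frame(species_id = species_id, m,
             final_class = classify_locus(m$verdict, m$placement),
             stringsAsFactors = FALSE)
}

#' Summarise the species-level divide
#'
#' Counts locus classes per species and assigns each species to a side of
#' the divide: `"embedded"` when at least one embedded locus and no
#' independent pol III locus is present; `"polIII"` when at least one
#' independent pol III locus and no embedded locus is present; `"mixed"`
#' when both classes occur (a potential counterexample worth inspecting,
#' not an error); `"unresolved"` when neither occurs. The summary is
#' invariant to record order.
#'
#' @param records `data.frame` from [classify_loci()] (possibly several
#'   species row-bound), requiring `species_id` and `final_class`.
#' @return `data.frame`: `species_id`, `n_loci`, `n_embedded`,
#'   `n_independent`, `n_unresolved`, `group`.
#' @export
summarize_species <- function(records) {
  if (!nrow(records)) stop("empty classification table", call. = FALSE)
  rows <- lapply(split(records, records$species_id), function(r) {
    ne <- sum(r$final_class == "embedded_polII")
    ni <- sum(r$final_class == "independent_polIII")
    nu <- sum(r$final_class == "unresolved")
    group <- if (ne > 0L && ni > 0L) "mixed"
      else if (ni > 0L) "polIII"
      else if (ne > 0L) "embedded"
      else "unresolved"
    data.frame(species_id = r$species_id[1], n_loci = nrow(r),
               n_embedded = ne, n_independent = ni, n_unresolved = nu,
               group = group, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
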