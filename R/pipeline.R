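## End-to-end orchestration: model fitting, promoter scan, context
## resolution, classification, species summary, optional density and
## signature validation, with a reproducibility manifest.

check_file <- function(path, what) {
  if (is.null(path)) return(NULL)
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  path
}

#' Run the full classification pipeline
#'
#' Executes, per species: promoter-model fitting from the training
#' promoters, the pol III promoter scan over all candidate loci, genomic
#' context resolution, locus and species classification, cohabitation
#' grouping and signature validation; optionally a read-density report.
#' All result tables are written as TSV to `out_dir` along with a
#' `manifest.yaml` recording parameters, seed and input checksums. Given
#' the same config and seed, outputs are byte-identical across runs.
#'
#' @param config path to a YAML config, or an equivalent named list.
#'   Top-level fields:
#'   \describe{
#'     \item{species}{list of entries with `id`, `genome` (FASTA),
#'       `annotation` (GFF3), `candidates` (BED6), `promoters` (FASTA).}
#'     \item{model}{optional: `pseudocount`, `margin`, `pse_seed`,
#'       `tata_seed`, `tata_offset_window`, `pse_search_window`.}
#'     \item{scan}{optional: `min_run`, `proximal_window`,
#'       `downstream_scan`, `abox`, `bbox`.}
#'     \item{density}{optional: `counts` (TSV) and `reference`
#'       (interval_id).}
#'     \item{seed}{integer, recorded in the manifest.}
#'     \item{out_dir}{output directory.}
#'   }
#' @param out_dir overrides `config$out_dir`.
#' @param seed overrides `config$seed`.
#' @return (invisibly) list with the result tables (`evidence`, `context`,
#'   `classification`, `species_summary`, `cohabitants`, `validation`,
#'   optionally `density`) and `paths` to the written files.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    check_file(config, "config")
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out_dir %||%
    stop("no output directory given", call. = FALSE)
  seed <- seed %||% config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$species) || !length(config$species))
    stop("config lists no species", call. = FALSE)

  defs <- polr3_defaults()
  mp <- config$model %||% list()
  sp <- config$scan %||% list()
  sigs <- signature_set(unlist(config$signatures %||% defs$signatures))

  evidence <- context <- classification <- cohab <- validation <- list()
  inputs <- character(0)
  for (s in config$species) {
    for (f in c("genome", "annotation", "candidates", "promoters"))
      check_file(s[[f]], paste(s$id, f))
    inputs <- c(inputs, unlist(s[c("genome", "annotation", "candidates",
                                   "promoters")]))
    genome <- read_genome(s$genome)
    loci <- read_loci_bed(s$candidates)
    ann <- read_annotation(s$annotation)
    model <- promoter_model(
      s$promoters,
      pse_seed = mp$pse_seed %||% defs$pse_consensus,
      tata_seed = mp$tata_seed %||% defs$tata_consensus,
      pseudocount = mp$pseudocount %||% 0.25,
      margin = mp$margin %||% 0,
      tata_offset_window = unlist(mp$tata_offset_window %||%
                                    defs$tata_offset_window),
      pse_search_window = unlist(mp$pse_search_window %||%
                                   defs$pse_search_window))
    ev <- scan_loci(genome, loci, model,
                    min_run = sp$min_run %||% defs$min_run,
                    proximal_window = sp$proximal_window %||%
                      defs$proximal_window,
                    downstream_scan = sp$downstream_scan %||% 60L,
                    abox = sp$abox %||% defs$abox,
                    bbox = sp$bbox %||% defs$bbox)
    cx <- resolve_context(loci, ann)
    evidence[[s$id]] <- data.frame(species_id = s$id, ev,
                                   stringsAsFactors = FALSE)
    context[[s$id]] <- data.frame(species_id = s$id, cx,
                                  stringsAsFactors = FALSE)
    classification[[s$id]] <- classify_loci(ev, cx, species_id = s$id)
    ch <- find_cohabitants(cx, loci)
    if (nrow(ch))
      cohab[[s$id]] <- data.frame(species_id = s$id, ch,
                                  stringsAsFactors = FALSE)
    validation[[s$id]] <- data.frame(species_id = s$id,
                                     verify_candidates(genome, loci, sigs),
                                     stringsAsFactors = FALSE)
  }

  res <- list(
    evidence = do.call(rbind, unname(evidence)),
    context = do.call(rbind, unname(context)),
    classification = do.call(rbind, unname(classification)),
    cohabitants = if (length(cohab)) do.call(rbind, unname(cohab)) else NULL,
    validation = do.call(rbind, unname(validation))
  )
  res$species_summary <- summarize_species(res$classification)

  if (!is.null(config$density)) {
    counts <- read_counts_tsv(check_file(config$density$counts,
                                         "density counts"))
    inputs <- c(inputs, config$density$counts)
    res$density <- if (!is.null(config$density$reference))
      fold_enrichment_table(counts, config$density$reference)
    else density_table(counts)
  }

  paths <- list()
  for (nm in c("evidence", "context", "classification", "cohabitants",
               "validation", "species_summary", "density")) {
    if (is.null(res[[nm]])) next
    paths[[nm]] <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(res[[nm]], paths[[nm]], seed = seed)
  }
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(
    package = "polr3class",
    version = as.character(utils::packageVersion("polr3class")),
    seed = as.integer(seed),
    parameters = list(model = mp, scan = sp),
    inputs = lapply(setNames(inputs, basename(inputs)), function(p)
      unname(tools::md5sum(p)))
  ), paths$manifest)

  res$paths <- paths
  invisible(res)
}
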