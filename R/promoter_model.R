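#' Default motif strings and scan parameters
#'
#' Returns the package defaults used where a species-specific value is not
#' supplied: a PSE-like 14-mer and TATAAA seed consensus for anchoring
#' promoter training sequences, tRNA-like A-box and B-box internal pol III
#' recognition motifs, and the diagnostic signature motifs used to verify
#' RPR/MRP candidates. The PSE seed and the mCR-I/mCR-V strings are
#' editable placeholders: published species consensi are not available, so
#' production use should supply consensus strings derived from the species
#' under study.
#'
#' @return named list: `pse_consensus`, `tata_consensus`, `abox`, `bbox`,
#'   `signatures` (named IUPAC motifs), `tata_offset_window`,
#'   `pse_search_window`, `min_run`, `proximal_window`.
#' @export
polr3_defaults <- function() {
  list(
    pse_consensus = "TTACCGTAACTTGA",
    tata_consensus = "TATAAA",
    abox = "TGGCNNAGTGG",
    bbox = "GTTCGANNC",
    signatures = c(GARAR = "GARAR",
                   mCR_I = "GRGGAAAGTCC",
                   mCR_V = "TGYGGAKAACG"),
    tata_offset_window = c(21L, 27L),
    pse_search_window = c(45L, 80L),
    min_run = 4L,
    proximal_window = 30L
  )
}

## Anchor each (unaligned) training sequence by its best-scoring window
## under a PWM built from the single seed consensus, and return the
## extracted equal-length site strings. This stands in for a full multiple
## alignment: sites share the seed consensus up to per-site noise, so the
## best seed-PWM window locates them.
anchor_sites <- function(training, seed_consensus, pseudocount, background) {
  seed_pwm <- build_pwm(seed_consensus, pseudocount = pseudocount,
                        background = background)
  vapply(training, function(s) {
    sc <- score_all_windows(seed_pwm, s)
    if (!length(sc))
      stop(sprintf("training sequence shorter than seed motif (%d nt)",
                   seed_pwm$length), call. = FALSE)
    at <- as.integer(names(sc)[which.max(sc)])
    substr(s, at, at + seed_pwm$length - 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Fit a species promoter model from U6/7SK training promoters
#'
#' Builds position weight matrices for the proximal sequence element (PSE)
#' and the TATA box of the pol III type-3 promoter from a set of training
#' promoter sequences (typically the upstream regions of a species' U6 and
#' 7SK snRNA genes), and calibrates a score threshold for each motif.
#'
#' If `aligned = FALSE` (default), each training sequence is first anchored
#' by the best-scoring window under a single-sequence seed PWM built from
#' `pse_seed` / `tata_seed`; the anchored site strings are then stacked into
#' the final PWMs. If `aligned = TRUE`, the sequences must be equal length
#' and the sites are extracted at fixed offsets `pse_offset` / `tata_offset`
#' (1-based).
#'
#' Thresholds are calibrated with [calibrate_threshold()]: the minimum over
#' training sequences of the best window score, minus `margin`, so every
#' training promoter passes its own model at margin 0.
#'
#' @param training character vector, `DNAStringSet`, or path to a FASTA
#'   file of training promoter sequences.
#' @param pse_seed,tata_seed seed consensus strings used for anchoring
#'   (defaults from [polr3_defaults()]).
#' @param pseudocount,background passed to [build_pwm()].
#' @param margin calibration slack in bits (default 0).
#' @param tata_offset_window inclusive gap window (nt between the TATA
#'   match's last base and the locus's first base) that counts as an
#'   "appropriately positioned" TATA; default `c(21, 27)`.
#' @param pse_search_window inclusive window of upstream distances (nt from
#'   the PSE's first base to the locus's first base) searched for the PSE;
#'   default `c(45, 80)`.
#' @param aligned logical; `TRUE` if `training` is pre-aligned.
#' @param pse_offset,tata_offset 1-based site offsets when `aligned = TRUE`.
#' @return object of class `"promoter_model"`: list with `pse` and `tata`
#'   PWMs, `pse_threshold`, `tata_threshold` (bits), `tata_offset_window`,
#'   `pse_search_window`, and the fit parameters.
#' @examples
#' train <- c("GATTACAGGTTACCGTAACTTGACCAGGTATAAAGGTACGATCA",
#'            "CCGTTACAGGTTACCGTAACTTGAGCAGGTATAAAGCTACGTAA")
#' m <- promoter_model(train)
#' m$tata_threshold
#' @export
promoter_model <- function(training,
                           pse_seed = polr3_defaults()$pse_consensus,
                           tata_seed = polr3_defaults()$tata_consensus,
                           pseudocount = 0.25,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           margin = 0,
                           tata_offset_window = c(21L, 27L),
                           pse_search_window = c(45L, 80L),
                           aligned = FALSE,
                           pse_offset = NULL, tata_offset = NULL) {
  if (is.character(training) && length(training) == 1L && file.exists(training))
    training <- Biostrings::readDNAStringSet(training)
  if (methods::is(training, "DNAStringSet")) training <- as.character(training)
  if (!length(training)) stop("empty training set", call. = FALSE)
  training <- toupper(unname(training))
  background <- check_background(background)
  if (tata_offset_window[1] > tata_offset_window[2] ||
      pse_search_window[1] > pse_search_window[2])
    stop("offset windows must be non-empty inclusive pairs", call. = FALSE)

  if (aligned) {
    if (is.null(pse_offset) || is.null(tata_offset))
      stop("'pse_offset' and 'tata_offset' are required when aligned = TRUE",
           call. = FALSE)
    pse_sites <- substr(training, pse_offset,
                        pse_offset + nchar(pse_seed) - 1L)
    tata_sites <- substr(training, tata_offset,
                         tata_offset + nchar(tata_seed) - 1L)
  } else {
    pse_sites <- anchor_sites(training, pse_seed, pseudocount, background)
    tata_sites <- anchor_sites(training, tata_seed, pseudocount, background)
  }

  pse <- build_pwm(pse_sites, pseudocount = pseudocount, background = background)
  tata <- build_pwm(tata_sites, pseudocount = pseudocount, background = background)
  structure(
    list(pse = pse, tata = tata,
         pse_threshold = calibrate_threshold(pse, training, margin),
         tata_threshold = calibrate_threshold(tata, training, margin),
         tata_offset_window = as.integer(tata_offset_window),
         pse_search_window = as.integer(pse_search_window),
         pseudocount = pseudocount, margin = margin,
         n_training = length(training)),
    class = "promoter_model"
  )
}

#' @export
print.promoter_model <- function(x, ...) {
  cat("Pol III type-3 promoter model\n")
  cat(sprintf("  trained on %d promoter sequence(s), pseudocount %g, margin %g bits\n",
              x$n_training, x$pseudocount, x$margin))
  cat(sprintf("  PSE : %s  (threshold %.2f bits, searched %d-%d nt upstream)\n",
              consensus_iupac(x$pse), x$pse_threshold,
              x$pse_search_window[1], x$pse_search_window[2]))
  cat(sprintf("  TATA: %s  (threshold %.2f bits, positioned gap %d-%d nt)\n",
              consensus_iupac(x$tata), x$tata_threshold,
              x$tata_offset_window[1], x$tata_offset_window[2]))
  invisible(x)
}

#' @export
summary.promoter_model <- function(object, ...) {
  print(object)
  cat("\nPSE probabilities:\n")
  print(round(object$pse$probs, 3))
  cat("\nTATA probabilities:\n")
  print(round(object$tata$probs, 3))
  invisible(object)
}

#' Scan candidate loci with a fitted promoter model
#'
#' `predict()` on a [`promoter_model`][promoter_model()] runs the full
#' per-locus promoter scan ([scan_loci()]) and returns the evidence table.
#'
#' @param object a fitted `promoter_model`.
#' @param genome `DNAStringSet` (or FASTA path).
#' @param loci `GRanges` of candidate loci (or BED6 path).
#' @param ... passed to [scan_loci()].
#' @return the evidence `data.frame` of [scan_loci()].
#' @export
predict.promoter_model <- function(object, genome, loci, ...) {
  scan_loci(genome, loci, object, ...)
}

#' Serialize / read a promoter model as plain text
#'
#' The model is written as a small versioned YAML document with
#' probabilities rounded to 6 decimals; [read_promoter_model()] restores a
#' working `promoter_model` (probabilities are re-normalised to absorb the
#' rounding).
#'
#' @param model a `promoter_model`.
#' @param path output file.
#' @return `write_promoter_model()` returns `path` invisibly;
#'   `read_promoter_model()` returns a `promoter_model`.
#' @export
write_promoter_model <- function(model, path) {
  stopifnot(inherits(model, "promoter_model"))
  dump_pwm <- function(p) list(
    probs = lapply(seq_len(p$length), function(j)
      as.list(round(p$probs[, j], 6))),
    background = as.list(round(p$background, 6)),
    pseudocount = p$pseudocount, nseq = p$nseq
  )
  yaml::write_yaml(list(
    format = "polr3class_promoter_model", version = 1L,
    pse = dump_pwm(model$pse), tata = dump_pwm(model$tata),
    pse_threshold = model$pse_threshold,
    tata_threshold = model$tata_threshold,
    tata_offset_window = as.integer(model$tata_offset_window),
    pse_search_window = as.integer(model$pse_search_window),
    pseudocount = model$pseudocount, margin = model$margin,
    n_training = model$n_training
  ), path)
  invisible(path)
}

#' @rdname write_promoter_model
#' @export
read_promoter_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$format, "polr3class_promoter_model"))
    stop("not a polr3class promoter model file: ", path, call. = FALSE)
  load_pwm <- function(d) {
    probs <- vapply(d$probs, function(col) unlist(col)[.BASES], numeric(4))
    probs <- sweep(probs, 2L, colSums(probs), "/")
    rownames(probs) <- .BASES
    structure(list(probs = probs,
                   background = check_background(unlist(d$background)),
                   pseudocount = d$pseudocount, nseq = d$nseq,
                   length = ncol(probs)),
              class = "pwm")
  }
  structure(
    list(pse = load_pwm(y$pse), tata = load_pwm(y$tata),
         pse_threshold = y$pse_threshold, tata_threshold = y$tata_threshold,
         tata_offset_window = as.integer(unlist(y$tata_offset_window)),
         pse_search_window = as.integer(unlist(y$pse_search_window)),
         pseudocount = y$pseudocount, margin = y$margin,
         n_training = y$n_training),
    class = "promoter_model"
  )
}
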