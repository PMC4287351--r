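---
title: "Detecting pol III type-3 promoter architecture and host-gene embedding of ncRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pol III type-3 promoter architecture and host-gene embedding of ncRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Small non-coding RNA genes such as the RNA subunits of RNase P (RPR) and
RNase MRP are classically transcribed by RNA polymerase III from a
gene-external "type-3" promoter: a proximal sequence element (PSE) and a
TATA box a short, fixed distance upstream of the transcript, with
transcription terminated at a run of T residues just downstream of the
gene. In insects and crustaceans, however, RPR genes lack all of these
signals and instead sit inside an intron of a highly expressed,
polymerase II-transcribed host ("recipient") gene, depending on the host
promoter for expression. Whether a given candidate locus is an
independent pol III unit or an embedded, promoterless gene is therefore a
concrete, decidable sequence-analysis question, and `polr3class`
implements it as a reproducible pipeline:

1. fit species-specific PSE and TATA position weight matrices (PWMs) from
   U6/7SK promoter training sequences (`promoter_model()`);
2. scan each candidate locus for a PSE, a positionally constrained TATA
   box, a 3' poly-T terminator and internal A-box/B-box elements, and
   assemble a pol III verdict (`scan_loci()`);
3. resolve each locus against the gene annotation — intronic vs
   intergenic, recipient gene, intron ordinal, orientation, tandem copies
   (`resolve_context()`, `find_cohabitants()`);
4. combine verdict and context into a per-locus and per-species
   classification (`classify_loci()`, `summarize_species()`).

A read-density module (`fold_enrichment()` and friends) supports the
expression side of the argument: an intronically encoded, independently
stable ncRNA shows a higher read density over its interval than the
preceding intron of the same host gene. Signature-motif validation
(`verify_candidates()`) checks that candidates are bona fide RPR/MRP-like
RNAs before any promoter interpretation is attempted.

## The promoter model

Each motif is a PWM with per-position probabilities
$p_{ij} = (c_{ij} + \alpha) / (n + 4\alpha)$, where $c_{ij}$ are base
counts over the training sites, $\alpha$ is a pseudocount (default 0.25)
and $n$ the number of sites. A window is scored in bits as
$\sum_j \log_2(p_{ij}/b_i)$ against a background $b$ (default uniform;
an `N` contributes 0 bits, so assembly gaps are neutral). These are
standard choices; nothing in the method depends on them finely, and both
are exposed as arguments.

Training input is typically unaligned upstream regions of a species' U6
and 7SK genes. Rather than running a multiple alignment, each sequence is
*anchored*: a single-sequence seed PWM built from a supplied seed
consensus locates the best-scoring window in each training sequence, and
the extracted windows are stacked into the final PWM. This preserves the
intent of building a species consensus from an alignment of U6/7SK
promoters while keeping alignment software out of the pipeline; it
assumes the training sites differ from the seed only by per-site
substitutions, which is exactly what the synthetic generator emulates and
a reasonable first approximation for real promoters of one species. A
pre-aligned mode (`aligned = TRUE` with fixed site offsets) is available
when curated alignments exist.

No published score cutoff exists for these motifs, so thresholds are
calibrated from the training set itself: the threshold is the minimum
over training sequences of the best window score, minus a slack `margin`
(default 0 bits). Every training promoter thus passes its own model, and
the model generalises exactly as far as its weakest training example —
a deliberately conservative rule that produces very high thresholds for
noise-free training sets and progressively laxer ones as training
diversity grows.

## Positional rules

Three rules carry the biological specificity, all config-exposed:

* **TATA gap window, default [21, 27] nt, inclusive.** The gap is counted
  as the number of bases strictly between the last base of the TATA match
  and the first base of the locus. The published observation names a
  distance range but not its anchor; this anchor (match 3' end, gap
  exclusive of both endpoints) is a declared convention, not an inferred
  one, and can be overridden together with the window. A TATA hit outside
  the window is still reported, but flagged `positioned = FALSE`.
* **PSE search window, default [45, 80] nt upstream** (distance from PSE
  first base to locus first base). The PSE must lie upstream of the TATA
  region; no published coordinates exist, so the window is a package
  default chosen to sit clear of the TATA gap region (a TATA at gap 27
  with a 6 nt box ends 33 nt upstream).
* **Poly-T terminator, minimum run 4, no maximum; proximal within
  30 bp.** Runs of 4–5 T are the canonical terminator; longer runs are
  stronger terminators, not violations. Because poly-T runs at variable
  distances occur even in signal-free genes, the terminator is recorded
  as *supporting evidence only*: the verdict is
  `polIII_positive` if and only if a PSE hit is present *and* the TATA
  hit is positioned. Internal A-box/B-box hits (tRNA-type promoters) are
  likewise recorded but do not gate the verdict; their consensus strings
  are editable defaults.

Minus-strand loci are scanned on the reverse complement, so all calls are
strand-symmetric by construction (and verified to be, on every synthetic
locus).

## Genomic context and the divide

Coordinates are handled in the R/Bioconductor convention — 1-based,
closed intervals, `GRanges` throughout — with BED's 0-based half-open
intervals converted at the boundary by `rtracklayer`. Using the host
language's native convention, rather than carrying a second internal one,
is the package's single-convention guard against off-by-one drift.

A locus is `intronic` when it lies fully inside one intron of the
recipient's main transcript (the longest, when several are annotated —
a declared simplification), `intergenic` when it overlaps no gene (both
flanking genes are reported, with genome edges marked), and
`overlapping_exon` otherwise; exon-overlapping placements are reported
but never classified, since no such case is defined by the underlying
observations. Intron ordinals are counted 5'→3' on the recipient strand.
Cohabiting loci (same recipient gene) are grouped; `tandem` requires at
least two members in the same intron with the same orientation.

The final mapping is deliberately simple and auditable:

| verdict | placement | class |
|---|---|---|
| positive | any | `independent_polIII` |
| negative | intronic | `embedded_polII` |
| negative | other | `unresolved` |

A pol III-positive locus inside an intron (the centipede arrangement —
an independent pol III gene that happens to sit in an intron, in opposite
orientation) is classified by its signals, not its placement; orientation
is reported but never gates the call. A species is assigned to the
embedded side of the divide when it has at least one embedded locus and
no independent one, to the pol III side in the converse case, and is
flagged `mixed` when both occur — the pipeline must be able to surface a
counterexample rather than assume the divide.

## The synthetic generator

`generate_species()` emits seeded species with the statistical structure
the classifier assumes, so that every stage is testable without genome
downloads: i.i.d. background sequence at a configured GC fraction (the
simplest null consistent with the PWM background model), host genes with
sampled exon/intron geometry, embedded loci placed fully inside introns
(capacity-aware assignment, bounded-retry placement, hard errors naming
the gene when geometry cannot fit), and intergenic loci carrying the full
planted cassette: PSE at a sampled distance in [45, 80], TATA at a
sampled gap in [21, 27], and a poly-T run of 4–5 T within the proximal
window, with intervening sequence scrubbed of spurious T-runs. All loci
carry planted signature-motif instances so candidate validation passes.

Default problem sizes — 30 kb genomes, 3 host genes, ~300 nt loci,
500–800 nt introns, 12 training promoters — are chosen as the smallest
sizes at which every structural feature of the real problem (multiple
introns, cohabitation, flanking genes, edge cases) occurs; panels of six
species with five loci each exercise the species-level divide.

Two modelling choices deserve emphasis:

* `promoter_noise` perturbs the *training promoters*, not the planted
  locus signals, which are exact consensus instances. This keeps every
  recorded signal position literally re-findable in the emitted FASTA
  (the truth-audit invariant) and means noise probes the calibration
  path: noisier training lowers thresholds, degrading *specificity*,
  while recall of planted loci stays at ceiling — which the acceptance
  check asserts as non-increase. Locus-side sequence divergence is a
  different (real) phenomenon the generator deliberately does not model.
* Read counts are Poisson with mean `density × length`. The provenance
  of real tiling/RNA-seq counts is unspecified upstream, so Poisson is a
  stand-in with the stated expectation, flagged as such; the density
  module itself is distribution-free arithmetic.

What passing round-trip tests therefore show is that the *decision
logic* is correct under its own assumptions — not that the thresholds
transfer to real genomes, where promoter divergence, assembly gaps and
annotation errors all bite. The signature-motif defaults for mCR-I/mCR-V
are likewise placeholders (the diagnostic regions are named but not
printed in the source literature) and should be replaced for production
use.

## Numerical and degenerate-input choices

* Ties in window scanning break toward the smaller start, making scans
  deterministic.
* `calibrate_threshold()` uses `>=` comparisons, so a training sequence
  exactly at threshold passes.
* Empty downstream sequence yields an absent terminator, not an error;
  an upstream context shorter than the scan window is an error naming
  the required length, because silently truncating the PSE window would
  bias verdicts negative.
* Zero reference density in `fold_enrichment()` is an explicit error;
  density records require positive lengths.
* PWM serialization rounds probabilities to 6 decimals; columns are
  re-normalised on read.

## Reproducing the analysis

```{r, eval = FALSE}
library(polr3class)

# a six-species noise-free panel, classified end to end
pan <- generate_panel(tempfile(), seed = 101)
res <- run_pipeline(list(
  species = lapply(pan$species, function(s)
    c(list(id = s$species_id),
      s$paths[c("genome", "annotation", "candidates", "promoters")])),
  out_dir = tempfile(), seed = 101))
table(res$classification$final_class, res$classification$species_id)
res$species_summary
```

`scripts/acceptance.R` in the source repository re-runs the full set of
headline computations (fold enrichments from the published read counts,
panel round-trip precision/recall, species divide accuracy, recall under
training noise) and writes them as JSON.

## Limitations

* The PWM background is 0-order; dinucleotide composition (e.g. TA-rich
  isochores) can inflate TATA scores in AT-rich genomes.
* Context resolution trusts the annotation; an unannotated host gene
  makes an embedded locus look intergenic (and hence `unresolved`, as in
  the poorly annotated body-louse case).
* Multi-transcript genes are resolved against the longest transcript
  only.
* Homology search, secondary-structure scoring and cross-species
  recipient-gene orthology are out of scope; candidates enter as BED
  intervals from upstream tools.
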