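# Oracles here are deliberately naive: exhaustive window enumeration,
# character loops and regex expansion, independent of the scan code.

test_that("best-hit scanning finds planted motifs and honours ties", {
  pwm <- build_pwm(rep("TATAAA", 4), pseudocount = 0)
  seq <- paste0(flat_bg(30), "TATAAA", flat_bg(20))
  hit <- scan_best_hit(pwm, seq, threshold = 6)
  expect_equal(hit$start, 31)
  expect_equal(hit$score, 12)

  # nothing above threshold -> absent
  expect_null(scan_best_hit(pwm, flat_bg(50), threshold = 0))

  # two equal-scoring copies: the smaller start wins, matching an
  # exhaustive enumeration oracle
  seq2 <- paste0(flat_bg(10), "TATAAA", flat_bg(10), "TATAAA", flat_bg(10))
  hit2 <- scan_best_hit(pwm, seq2, threshold = 6)
  scores <- vapply(seq_len(nchar(seq2) - 5),
                   function(i) score_window(pwm, seq2, i), numeric(1))
  expect_equal(hit2$start, which(scores == max(scores))[1])
  expect_equal(hit2$start, 11)

  # window restriction excludes the first copy
  hit3 <- scan_best_hit(pwm, seq2, threshold = 6, window = c(20, 40))
  expect_equal(hit3$start, 27)

  expect_error(scan_best_hit(pwm, seq2, 0, window = c(5, 2)), "window")
})

test_that("TATA positioning uses an inclusive 21-27 gap window", {
  m <- make_model(noise = 0, seed = 2)
  up_with_gap <- function(gap) {
    paste0(flat_bg(60), DEFS$tata_consensus, flat_bg(gap))
  }
  for (gap in c(21, 24, 27)) {
    r <- scan_tata_positioned(up_with_gap(gap), m)
    expect_true(r$positioned, info = paste("gap", gap))
    expect_equal(r$hit$gap, gap)
  }
  for (gap in c(20, 28, 40)) {
    r <- scan_tata_positioned(up_with_gap(gap), m)
    expect_false(r$positioned, info = paste("gap", gap))
    expect_equal(r$hit$gap, gap)   # hit still reported, just not positioned
  }
  # brute-force oracle: enumerate all windows, compute gaps directly
  up <- up_with_gap(24)
  gaps <- nchar(up) - (seq_len(nchar(up) - 5) + 5)
  scores <- vapply(seq_len(nchar(up) - 5),
                   function(i) score_window(m$tata, up, i), numeric(1))
  oracle <- any(scores >= m$tata_threshold & gaps >= 21 & gaps <= 27)
  expect_equal(scan_tata_positioned(up, m)$positioned, oracle)

  expect_error(scan_tata_positioned(flat_bg(20), m), "too short")
})

test_that("poly-T terminator calling finds the first qualifying run", {
  r <- scan_polyT("TTTTGCCAG")
  expect_equal(r$run_start, 0)
  expect_equal(r$run_length, 4)
  expect_true(r$proximal)

  expect_null(scan_polyT("TTTAGGCAG"))          # run of 3 < 4
  expect_null(scan_polyT(""))

  r5 <- scan_polyT(paste0(flat_bg(50), "TTTTT", flat_bg(10)),
                   proximal_window = 30)
  expect_equal(r5$run_start, 50)
  expect_equal(r5$run_length, 5)
  expect_false(r5$proximal)

  # character-loop oracle on random sequences
  set.seed(99)
  for (i in 1:50) {
    s <- rnd_dna(60, bases = c("A", "T", "T", "G"))  # T-rich to force runs
    got <- scan_polyT(s, min_run = 4, proximal_window = 20)
    want <- polyT_oracle(s, 4)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got$run_start, unname(want["start"]))
      expect_equal(got$run_length, unname(want["len"]))
      expect_equal(got$proximal, want["start"] <= 20, ignore_attr = TRUE)
    }
  }
})

test_that("internal promoter requires A-box before B-box", {
  a <- "TGGCTTAGTGG"   # matches the A-box consensus TGGCNNAGTGG
  b <- "GTTCGAGGC"     # matches the B-box consensus GTTCGANNC
  expect_true(scan_internal_promoter(paste0(flat_bg(10), a, flat_bg(20),
                                            b, flat_bg(10)))$found)
  expect_false(scan_internal_promoter(paste0(flat_bg(10), b, flat_bg(20),
                                             a, flat_bg(10)))$found)
  expect_false(scan_internal_promoter(flat_bg(80))$found)
  expect_error(scan_internal_promoter("ACGT", abox = "TXX"), "IUPAC")

  # brute-force match-pair oracle over random sequences
  set.seed(7)
  for (i in 1:200) {
    s <- rnd_dna(120)
    if (runif(1) < 0.5) {  # plant motifs in half the cases
      at <- sample(1:60, 2)
      substr(s, at[1], at[1] + nchar(a) - 1) <- a
      substr(s, at[2], at[2] + nchar(b) - 1) <- b
    }
    av <- iupac_oracle(DEFS$abox, s)
    bv <- iupac_oracle(DEFS$bbox, s)
    oracle <- any(vapply(av, function(x)
      any(bv > x + nchar(DEFS$abox) - 1), logical(1)))
    expect_equal(scan_internal_promoter(s)$found, oracle, info = i)
  }
})

test_that("the verdict is PSE AND positioned TATA; the rest is supporting", {
  hit <- list(start = 1, score = 10, length = 6)
  term <- list(run_start = 2, run_length = 4, proximal = TRUE)
  # truth table over all 8 combinations of the three binary inputs
  for (has_pse in c(TRUE, FALSE))
    for (positioned in c(TRUE, FALSE))
      for (has_term in c(TRUE, FALSE)) {
        st <- assemble_polIII_evidence(
          pse_hit = if (has_pse) hit else NULL,
          tata = list(hit = hit, positioned = positioned),
          terminator = if (has_term) term else NULL)
        expect_equal(st$verdict == "polIII_positive",
                     has_pse && positioned)
      }
  # the S2-style pattern: distal poly-T alone never rescues a verdict
  st <- assemble_polIII_evidence(NULL, list(hit = NULL, positioned = FALSE),
                                 list(run_start = 40, run_length = 5,
                                      proximal = FALSE))
  expect_equal(st$verdict, "polIII_negative")
  expect_output(print(st), "polIII_negative")
})

test_that("minus-strand loci scan identically to their mirrored construction", {
  sp <- quick_species(seed = 31, n_embedded_loci = 2,
                      n_independent_loci = 3)
  genome <- read_genome(sp$paths$genome)
  loci <- read_loci_bed(sp$paths$candidates)
  m <- promoter_model(sp$paths$promoters)
  ev <- scan_loci(genome, loci, m)

  # mirror the whole chromosome and all loci
  n <- Biostrings::width(genome)[1]
  rc <- Biostrings::reverseComplement(genome)
  loci_rc <- GenomicRanges::GRanges(
    names(genome),
    IRanges::IRanges(n - GenomicRanges::end(loci) + 1,
                     n - GenomicRanges::start(loci) + 1),
    strand = ifelse(as.character(GenomicRanges::strand(loci)) == "+",
                    "-", "+"),
    name = loci$name)
  names(rc) <- names(genome)
  ev_rc <- scan_loci(rc, loci_rc, m)
  ev_rc <- ev_rc[match(ev$locus_id, ev_rc$locus_id), ]
  rownames(ev_rc) <- NULL
  expect_equal(ev_rc, ev)
})
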