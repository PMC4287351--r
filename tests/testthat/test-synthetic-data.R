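test_that("config validation enforces the generation invariants", {
  expect_s3_class(species_config(), "species_config")
  expect_error(species_config(n_host_genes = -1), ">= 0")
  expect_error(species_config(exons_per_gene = 1), ">= 2")
  expect_error(species_config(gc_content = 1.2), "gc_content")
  expect_error(species_config(promoter_noise = 1), "promoter_noise")
  expect_error(species_config(tata_offset_range = c(27, 21)), "pair")
  expect_error(species_config(n_embedded_loci = 1, n_host_genes = 0),
               "host gene")
})

test_that("a species with no loci still emits genome and genes", {
  dir <- withr::local_tempdir()
  sp <- generate_species(species_config(n_embedded_loci = 0,
                                        n_independent_loci = 0, seed = 3),
                         dir, "bare")
  expect_equal(nrow(sp$truth), 0)
  expect_true(all(file.exists(unlist(sp$paths))))
  g <- read_genome(sp$paths$genome)
  expect_equal(unname(Biostrings::width(g)), 30000)
  ann <- read_annotation(sp$paths$annotation)
  expect_equal(length(ann$genes), 3)
})

test_that("generation is byte-deterministic for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- species_config(seed = 77, promoter_noise = 0.1)
  s1 <- generate_species(cfg, d1, "det")
  s2 <- generate_species(cfg, d2, "det")
  for (f in names(s1$paths)) {
    expect_equal(unname(tools::md5sum(s1$paths[[f]])),
                 unname(tools::md5sum(s2$paths[[f]])), info = f)
  }
  # and a different seed changes the genome
  s3 <- generate_species(species_config(seed = 78), withr::local_tempdir(),
                         "det")
  expect_false(unname(tools::md5sum(s3$paths$genome)) ==
                 unname(tools::md5sum(s1$paths$genome)))
})

test_that("planted signals are literally re-findable in the emitted FASTA", {
  sp <- quick_species(seed = 13, n_embedded_loci = 3,
                      n_independent_loci = 2)
  truth <- sp$truth
  expect_equal(sum(truth$planted_class == "embedded_polII"), 3)
  expect_equal(sum(truth$planted_class == "independent_polIII"), 2)
  chr <- read_genome(sp$paths$genome)[[1]]

  sense <- function(s, e, strand) {
    x <- as.character(Biostrings::subseq(chr, s, e))
    if (strand == "-")
      x <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(x)))
    x
  }
  ind <- truth[truth$planted_class == "independent_polIII", ]
  for (i in seq_len(nrow(ind))) {
    r <- ind[i, ]
    expect_true(r$tata_offset >= 21 && r$tata_offset <= 27)
    up <- if (r$strand == "+") sense(r$start - 80, r$start - 1, "+")
          else sense(r$end + 1, r$end + 80, "-")
    down <- if (r$strand == "+") sense(r$end + 1, r$end + 40, "+")
            else sense(r$start - 40, r$start - 1, "-")
    # literal substring oracles at the recorded offsets
    g <- r$tata_offset
    expect_equal(substr(up, 80 - g - 5, 80 - g), DEFS$tata_consensus)
    d <- r$pse_dist
    expect_equal(substr(up, 80 - d + 1, 80 - d + 14), DEFS$pse_consensus)
    ts <- r$terminator_start
    expect_equal(substr(down, ts + 1, ts + 4), "TTTT")
    # no earlier qualifying run than the planted one
    if (ts > 0)
      expect_false(grepl("T{4,}", substr(down, 1, ts)))
  }
  # embedded records carry no signal positions
  emb <- truth[truth$planted_class == "embedded_polII", ]
  expect_true(all(is.na(emb$pse_dist)))
  expect_true(all(is.na(emb$tata_offset)))
  expect_true(all(is.na(emb$terminator_start)))
  expect_true(all(!is.na(emb$recipient_gene_id)))
})

test_that("impossible sizing fails loudly and names the gene", {
  expect_error(
    generate_species(species_config(intron_length_range = c(120, 150),
                                    locus_length = 300, seed = 5),
                     withr::local_tempdir(), "tiny"),
    "intron of gene tiny_g")
  expect_error(
    generate_species(species_config(genome_length = 2000, seed = 5),
                     withr::local_tempdir(), "cramped"),
    "genome_length")
})

test_that("simulated read counts have the stated expectations", {
  # zero density means zero counts
  iv <- data.frame(interval_id = c("a", "b"), length = c(100, 200))
  z <- simulate_read_counts(iv, c(0, 0), seed = 1)
  expect_equal(z$count, c(0L, 0L))
  expect_error(simulate_read_counts(iv, c(1, -2)), "negative density")
  expect_error(simulate_read_counts(iv, 1), "match")

  # Monte-Carlo: one interval, length 1000, density 5 -> mean ~ 5000
  one <- data.frame(interval_id = "x", length = 1000)
  counts <- vapply(1:200, function(s)
    simulate_read_counts(one, 5, seed = s)$count, numeric(1))
  expect_lt(abs(mean(counts) - 5000) / 5000, 0.05)

  # planted density ratio 4.8 recovered within 10%
  two <- data.frame(interval_id = c("hi", "lo"), length = c(350, 680))
  ratios <- vapply(1:200, function(s) {
    d <- density_table(simulate_read_counts(two, c(4.8, 1.0), seed = s))
    d$density[1] / d$density[2]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4.8) / 4.8, 0.1)
})

test_that("panels plant the requested species-level divide", {
  pan <- generate_panel(withr::local_tempdir(), n_embedded_species = 2,
                        n_polIII_species = 2, loci_per_species = 3,
                        seed = 5)
  expect_equal(nrow(pan$truth), 12)
  expect_equal(pan$expected_groups$group, c("embedded", "embedded",
                                            "polIII", "polIII"))
  by_sp <- split(pan$truth$planted_class, pan$truth$species_id)
  expect_true(all(by_sp$sp01 == "embedded_polII"))
  expect_true(all(by_sp$sp04 == "independent_polIII"))
})
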