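# A small hand-written annotation: two genes on chrN (1..2000 and
# 3001..5000), the second on the minus strand, plus a per-base oracle for
# randomized placements.

write_test_gff3 <- function(lines) {
  path <- tempfile(fileext = ".gff3")   # session tempdir, cleaned on exit
  writeLines(c("##gff-version 3", lines), path)
  path
}

two_gene_gff3 <- function() {
  write_test_gff3(c(
    "chrN\ttest\tgene\t1\t2000\t.\t+\t.\tID=gA",
    "chrN\ttest\tmRNA\t1\t2000\t.\t+\t.\tID=gA_t1;Parent=gA",
    "chrN\ttest\texon\t1\t300\t.\t+\t.\tParent=gA_t1",
    "chrN\ttest\texon\t801\t1100\t.\t+\t.\tParent=gA_t1",
    "chrN\ttest\texon\t1701\t2000\t.\t+\t.\tParent=gA_t1",
    "chrN\ttest\tgene\t3001\t5000\t.\t-\t.\tID=gB",
    "chrN\ttest\tmRNA\t3001\t5000\t.\t-\t.\tID=gB_t1;Parent=gB",
    "chrN\ttest\texon\t3001\t3300\t.\t-\t.\tParent=gB_t1",
    "chrN\ttest\texon\t4001\t4300\t.\t-\t.\tParent=gB_t1",
    "chrN\ttest\texon\t4701\t5000\t.\t-\t.\tParent=gB_t1"
  ))
}

loci_gr <- function(starts, ends, strands, ids = NULL) {
  GenomicRanges::GRanges("chrN", IRanges::IRanges(starts, ends),
                         strand = strands,
                         name = ids %||% paste0("L", seq_along(starts)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("intronic, intergenic and exon-straddling loci are resolved", {
  ann <- read_annotation(two_gene_gff3())
  cx <- resolve_context(loci_gr(
    starts = c(1200, 3400, 2300, 1050),
    ends = c(1500, 3700, 2600, 1250),
    strands = c("+", "+", "+", "+")), ann)

  # plus-strand gene, locus in its final intron, same orientation
  expect_equal(cx$placement[1], "intronic")
  expect_equal(cx$recipient_gene_id[1], "gA")
  expect_equal(cx$intron_ordinal[1], 2)
  expect_true(cx$last_intron[1])
  expect_equal(cx$orientation[1], "same")
  expect_equal(cx$containment[1], "full")

  # minus-strand gene: genomic-leftmost intron is its LAST intron, and a
  # plus-strand locus inside it is in opposite orientation
  expect_equal(cx$placement[2], "intronic")
  expect_equal(cx$recipient_gene_id[2], "gB")
  expect_equal(cx$intron_ordinal[2], 2)
  expect_true(cx$last_intron[2])
  expect_equal(cx$orientation[2], "opposite")

  # between the two genes: both flanking neighbours reported
  expect_equal(cx$placement[3], "intergenic")
  expect_equal(cx$left_gene_id[3], "gA")
  expect_equal(cx$right_gene_id[3], "gB")

  # straddling an exon boundary
  expect_equal(cx$placement[4], "overlapping_exon")
  expect_equal(cx$containment[4], "partial")

  expect_error(resolve_context(
    GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10), strand = "+",
                           name = "x"), ann), "unknown sequence")
})

test_that("genome-edge intergenic loci get edge markers", {
  ann <- read_annotation(two_gene_gff3())
  cx <- resolve_context(loci_gr(c(5500), c(5700), "+"), ann)
  expect_equal(cx$left_gene_id, "gB")
  expect_equal(cx$right_gene_id, "genome_end")
})

test_that("intron ordinals reverse when the recipient strand flips", {
  plus <- read_annotation(two_gene_gff3())
  minus_lines <- c(
    "chrN\ttest\tgene\t1\t2000\t.\t-\t.\tID=gA",
    "chrN\ttest\tmRNA\t1\t2000\t.\t-\t.\tID=gA_t1;Parent=gA",
    "chrN\ttest\texon\t1\t300\t.\t-\t.\tParent=gA_t1",
    "chrN\ttest\texon\t801\t1100\t.\t-\t.\tParent=gA_t1",
    "chrN\ttest\texon\t1701\t2000\t.\t-\t.\tParent=gA_t1")
  minus <- read_annotation(write_test_gff3(minus_lines))
  l <- loci_gr(400, 700, "+")   # first genomic intron of gA
  k_plus <- resolve_context(l, plus)$intron_ordinal
  k_minus <- resolve_context(l, minus)$intron_ordinal
  n <- 2
  expect_equal(k_plus, 1)
  expect_equal(k_minus, n - k_plus + 1)
})

test_that("placement matches a per-base oracle on random annotations", {
  set.seed(123)
  for (rep in 1:8) {
    ra <- random_annotation(sample(2:6, 1))
    ann <- read_annotation(ra$path)
    starts <- sample(50:(ra$span + 200), 15)
    lens <- sample(20:120, 15, replace = TRUE)
    cx <- resolve_context(loci_gr(starts, starts + lens,
                                  sample(c("+", "-"), 15, TRUE)), ann)
    oracle <- vapply(1:15, function(i)
      placement_oracle(starts[i], starts[i] + lens[i], ra$genes),
      character(1))
    expect_equal(cx$placement, oracle, info = paste("rep", rep))
  }
})

test_that("cohabitation groups flag tandem and split copies", {
  ann <- read_annotation(two_gene_gff3())
  # two adjacent same-strand loci in gA's intron 1, one in gB's intron
  l <- loci_gr(starts = c(350, 500, 3400),
               ends = c(420, 570, 3700),
               strands = c("+", "+", "-"),
               ids = c("t1", "t2", "solo"))
  cx <- resolve_context(l, ann)
  ch <- find_cohabitants(cx, l)
  ch <- ch[order(ch$gene_id), ]
  expect_equal(ch$gene_id, c("gA", "gB"))
  expect_equal(ch$n_members, c(2L, 1L))
  expect_true(ch$tandem[ch$gene_id == "gA"])
  expect_true(ch$same_intron[ch$gene_id == "gA"])
  expect_equal(ch$members[ch$gene_id == "gA"], "t1,t2")
  expect_false(ch$tandem[ch$gene_id == "gB"])

  # same gene, different introns: grouped but neither same-intron nor tandem
  l2 <- loci_gr(c(350, 1200), c(420, 1300), c("+", "+"), c("a", "b"))
  ch2 <- find_cohabitants(resolve_context(l2, ann), l2)
  expect_equal(ch2$n_members, 2L)
  expect_false(ch2$same_intron)
  expect_false(ch2$tandem)

  # opposite orientations in one intron: cohabiting but not tandem
  l3 <- loci_gr(c(350, 500), c(420, 570), c("+", "-"), c("a", "b"))
  ch3 <- find_cohabitants(resolve_context(l3, ann), l3)
  expect_false(ch3$tandem)
  expect_true(ch3$same_intron)
})

test_that("synthetic embedded loci resolve to their planted recipients", {
  sp <- quick_species(seed = 41, n_embedded_loci = 4,
                      n_independent_loci = 1)
  cx <- resolve_context(read_loci_bed(sp$paths$candidates),
                        read_annotation(sp$paths$annotation))
  truth <- sp$truth
  emb <- truth[truth$planted_class == "embedded_polII", ]
  m <- match(emb$locus_id, cx$locus_id)
  expect_equal(cx$placement[m], rep("intronic", nrow(emb)))
  expect_equal(cx$recipient_gene_id[m], emb$recipient_gene_id)
  expect_equal(cx$intron_ordinal[m], emb$intron_ordinal)
})
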