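# Shared fixtures. Test-side random sequence and training generators are
# written independently of the package internals so they can serve as
# oracle plumbing.

DEFS <- polr3_defaults()

# random DNA without using package internals
rnd_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# deterministic TATA-free, PSE-free background of length n
flat_bg <- function(n) {
  substr(strrep("CGGACCGGAC", ceiling(n / 10)), 1, n)
}

# a training set whose PSE/TATA sites sit at known offsets
make_training <- function(n = 10, noise = 0, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    pse <- DEFS$pse_consensus
    tata <- DEFS$tata_consensus
    mut <- function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(runif(length(ch)) < noise)
      for (j in hit) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
      paste(ch, collapse = "")
    }
    paste0(rnd_dna(12), mut(pse), rnd_dna(24), mut(tata), rnd_dna(30))
  }, character(1))
}

make_model <- function(noise = 0, seed = 1, n = 10, ...) {
  promoter_model(make_training(n, noise, seed), ...)
}

# one small synthetic species, cached per (seed, ...) within a test run
quick_species <- function(seed = 11,
                          dir = withr::local_tempdir(.local_envir = parent.frame()),
                          ...) {
  generate_species(species_config(seed = seed, ...), dir,
                   sprintf("s%d", seed))
}
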