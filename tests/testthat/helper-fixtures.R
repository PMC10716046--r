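# Small in-code fixtures.

toy_genome <- function(seqs = c(c1 = "ACGT")) genome_store(seqs)

# A CTSS table built directly (0-based positions).
toy_ctss <- function(contig, pos, strand, counts, sample = "s1") {
  out <- data.frame(contig = contig, pos = as.integer(pos), strand = strand,
                    stringsAsFactors = FALSE)
  out[[paste0("count.", sample)]] <- as.integer(counts)
  out
}

# Attach tpm columns equal to given values (bypassing normalization).
with_tpm <- function(ctss, tpm, sample = "s1") {
  ctss[[paste0("tpm.", sample)]] <- tpm
  ctss
}

# Random genome string of length n (seeded by caller).
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

small_config <- function(seed = 11L, ...) {
  synthetic_config(seed = seed, n_promoters = 60L, n_contigs = 2L,
                   depth = 5e4, ...)
}
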