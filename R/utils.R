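# Internal helpers shared across modules.

# Vectorized reverse complement of plain character DNA (A/C/G/T/N).
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

is_pyrimidine <- function(b) b %in% PYRIMIDINES

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Column names holding per-sample values in a CTSS table.
count_cols <- function(ctss) grep("^count\\.", names(ctss), value = TRUE)
tpm_cols <- function(ctss) grep("^tpm\\.", names(ctss), value = TRUE)

ctss_samples <- function(ctss) sub("^count\\.", "", count_cols(ctss))

# Matrix of per-sample TPM (rows follow the table), zero-filled if absent.
ctss_tpm_matrix <- function(ctss, samples = NULL) {
  cols <- tpm_cols(ctss)
  if (is.null(samples)) samples <- sub("^tpm\\.", "", cols)
  m <- matrix(0, nrow = nrow(ctss), ncol = length(samples),
              dimnames = list(NULL, samples))
  for (s in samples) {
    cl <- paste0("tpm.", s)
    if (cl %in% names(ctss)) m[, s] <- ctss[[cl]]
  }
  m
}

ctss_count_matrix <- function(ctss) {
  cols <- count_cols(ctss)
  m <- as.matrix(ctss[, cols, drop = FALSE])
  colnames(m) <- sub("^count\\.", "", cols)
  m
}

# Canonical ordering used by all writers: contig, pos, strand.
order_ctss <- function(ctss) {
  ctss[order(ctss$contig, ctss$pos, ctss$strand), , drop = FALSE]
}
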