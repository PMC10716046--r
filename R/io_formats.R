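# Readers and writers for external formats, and the single home for
# coordinate conventions: everything internal is 0-based half-open,
# BED is native, GTF is converted on read.

#' Read a genome FASTA into a genome store
#'
#' Sequences are uppercase-normalized and held as plain character vectors
#' keyed by contig name. Only A/C/G/T/N are accepted.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome_store`: a named list with elements
#'   `seq` (named character vector of sequences) and `lengths`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stopf("duplicate FASTA headers: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  if (any(nchar(seqs) == 0L)) stopf("empty sequence in FASTA: %s",
                                    paste(nm[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stopf("non-ACGTN characters in contig(s): %s",
                      paste(nm[bad], collapse = ", "))
  genome_store(seqs)
}

#' Construct a genome store from named sequences
#'
#' @param seqs Named character vector, one DNA string per contig.
#' @return A `genome_store` object.
#' @export
genome_store <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  seqs <- toupper(seqs)
  structure(list(seq = seqs, lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "genome_store")
}

#' @export
print.genome_store <- function(x, ...) {
  cat("genome_store with", length(x$seq), "contig(s), total",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp\n")
  invisible(x)
}

#' Fetch a strand-oriented genome subsequence
#'
#' Coordinates are 0-based half-open. On the minus strand the reverse
#' complement of the plus-strand slice is returned, so that
#' `genome_fetch(g, c, s, e, "-")` equals the transcript-oriented read of
#' that interval. Out-of-range requests are an error, never a truncation.
#'
#' @param genome A `genome_store`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return A character scalar of length `end - start`.
#' @export
genome_fetch <- function(genome, contig, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome_store"))
  if (!contig %in% names(genome$seq)) stopf("unknown contig: %s", contig)
  len <- genome$lengths[[contig]]
  if (start < 0 || end > len || start > end)
    stopf("fetch out of range on %s: [%d,%d) with contig length %d",
          contig, start, end, len)
  s <- substr(genome$seq[[contig]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Read a single-sample CTSS table from BED6
#'
#' Dialect: each record is one CAGE transcription start site; `start` is
#' the 0-based 5' base, `end` must equal `start + 1`, and the score column
#' carries the raw tag count.
#'
#' @param path Path to a BED6 file.
#' @param sample Sample name; defaults to the file name without extension.
#' @return A data.frame with columns `contig`, `pos`, `strand` and
#'   `count.<sample>`.
#' @export
read_ctss_bed <- function(path, sample = NULL) {
  if (!file.exists(path)) stopf("CTSS BED file not found: %s", path)
  if (is.null(sample)) sample <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
    out[[paste0("count.", sample)]] <- integer(0)
    return(out)
  }
  f <- strsplit(lines, "\t| +")
  ncols <- lengths(f)
  if (any(ncols < 6L)) stopf("line %d: expected 6 BED columns, got %d",
                             which(ncols < 6L)[1], min(ncols))
  m <- do.call(rbind, lapply(f, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) stopf("non-integer coordinates in %s", path)
  bad <- which(end != start + 1L)
  if (length(bad)) stopf("line %d: CTSS interval must have width 1 (end = start + 1)",
                         bad[1])
  count <- suppressWarnings(as.numeric(m[, 5]))
  if (anyNA(count)) stopf("non-numeric score column in %s", path)
  if (any(count < 0)) stopf("line %d: negative tag count", which(count < 0)[1])
  strand <- m[, 6]
  if (!all(strand %in% c("+", "-"))) stopf("line %d: strand must be + or -",
                                           which(!strand %in% c("+", "-"))[1])
  out <- data.frame(contig = m[, 1], pos = start, strand = strand,
                    stringsAsFactors = FALSE)
  out[[paste0("count.", sample)]] <- as.integer(round(count))
  key <- paste(out$contig, out$pos, out$strand)
  if (anyDuplicated(key)) stopf("duplicate (contig,pos,strand) in %s", path)
  order_ctss(out)
}

#' Write a single sample of a CTSS table as BED6
#'
#' @param ctss CTSS table as from [read_ctss_bed()] or [merge_ctss()].
#' @param path Output path.
#' @param sample Sample whose raw counts populate the score column; defaults
#'   to the only sample present.
#' @export
write_ctss_bed <- function(ctss, path, sample = NULL) {
  samples <- ctss_samples(ctss)
  if (is.null(sample)) {
    if (length(samples) != 1L) stopf("table has %d samples; give `sample`",
                                     length(samples))
    sample <- samples
  }
  cnt <- ctss[[paste0("count.", sample)]]
  keep <- cnt > 0
  x <- order_ctss(ctss[keep, , drop = FALSE])
  lines <- sprintf("%s\t%d\t%d\t.\t%d\t%s", x$contig, x$pos, x$pos + 1L,
                   x[[paste0("count.", sample)]], x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Merge per-sample CTSS tables by position
#'
#' Outer join on (contig, pos, strand); counts absent in a sample are 0.
#'
#' @param tables List of single- or multi-sample CTSS tables.
#' @return A multi-sample CTSS table.
#' @export
merge_ctss <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  keyed <- lapply(tables, function(t) {
    t$.key <- paste(t$contig, t$pos, t$strand, sep = "\r")
    t
  })
  keys <- unique(unlist(lapply(keyed, `[[`, ".key")))
  first <- keyed[[1]]
  kv <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(contig = vapply(kv, `[`, "", 1L),
                    pos = as.integer(vapply(kv, `[`, "", 2L)),
                    strand = vapply(kv, `[`, "", 3L),
                    stringsAsFactors = FALSE)
  rownames(out) <- keys
  for (t in keyed) {
    for (cl in grep("^(count|tpm)\\.", names(t), value = TRUE)) {
      if (is.null(out[[cl]])) out[[cl]] <- 0
      out[keys %in% t$.key, cl] <- t[[cl]][match(keys[keys %in% t$.key], t$.key)]
    }
  }
  rownames(out) <- NULL
  order_ctss(out)
}

#' Read gene models from a GTF file
#'
#' One record is kept per gene id. The annotated TSS is the 5'-most
#' transcript start: `start - 1` (0-based) on the plus strand, `end - 1`
#' on the minus strand. The gene span is the union envelope of its
#' features, 0-based half-open.
#'
#' @param path Path to a GTF file with `gene` and/or `transcript` features
#'   carrying a `gene_id` attribute.
#' @return A data.frame with columns `gene_id`, `contig`, `strand`, `tss`,
#'   `start`, `end`.
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  types <- as.character(md$type)
  use <- types %in% c("gene", "transcript")
  if (!any(use)) use <- rep(TRUE, length(gr))
  gr <- gr[use]
  md <- S4Vectors::mcols(gr)
  gid <- as.character(md$gene_id)
  if (is.null(md$gene_id) || anyNA(gid) || any(gid == ""))
    stopf("GTF records lack a gene_id attribute: %s", path)
  df <- data.frame(gene_id = gid,
                   contig = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(BiocGenerics::strand(gr)),
                   start1 = BiocGenerics::start(gr),
                   end1 = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stopf("gene features must be stranded (+/-)")
  sp <- split(df, df$gene_id)
  rows <- lapply(sp, function(g) {
    start0 <- min(g$start1) - 1L
    end0 <- max(g$end1)
    tss <- if (g$strand[1] == "+") start0 else end0 - 1L
    data.frame(gene_id = g$gene_id[1], contig = g$contig[1],
               strand = g$strand[1], tss = tss, start = start0, end = end0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$contig, out$tss, out$gene_id), , drop = FALSE]
}

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts the standard JASPAR layout: a `>id name` header followed by four
#' rows (A, C, G, T) of non-negative counts, optionally bracketed. Columns
#' summing to zero are accepted but flagged via the `"zero_columns"`
#' attribute (a pseudocount is applied downstream).
#'
#' @param path Path to a JASPAR-format file, possibly with several motifs.
#' @return A named list of 4 x width numeric matrices (rows A, C, G, T),
#'   each carrying attributes `id` and `name`.
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stopf("JASPAR file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stopf("no JASPAR headers (>) found in %s", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    body <- lines[from:to]
    if (length(body) != 4L)
      stopf("motif %s: expected 4 base rows (A/C/G/T), got %d",
            lines[heads[i]], length(body))
    row_base <- toupper(sub("^([ACGTacgt]).*$", "\\1", body))
    labeled <- grepl("^[ACGTacgt][^0-9]", body) | grepl("^[ACGTacgt]$", body)
    vals <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]", "", l)
      l <- gsub("\\[|\\]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
      if (anyNA(v)) stopf("non-numeric PFM row in %s", path)
      v
    })
    if (all(labeled)) {
      if (!setequal(row_base, c("A", "C", "G", "T")))
        stopf("motif %s: rows must be labeled A, C, G and T", lines[heads[i]])
      vals <- vals[match(c("A", "C", "G", "T"), row_base)]
    }
    w <- unique(lengths(vals))
    if (length(w) != 1L)
      stopf("motif %s: rows of unequal length", lines[heads[i]])
    m <- do.call(rbind, vals)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(m < 0)) stopf("negative counts in PFM %s", lines[heads[i]])
    hdr <- strsplit(sub("^>", "", lines[heads[i]]), "[[:space:]]+")[[1]]
    attr(m, "id") <- hdr[1]
    attr(m, "name") <- if (length(hdr) > 1) hdr[2] else hdr[1]
    zc <- which(colSums(m) == 0)
    attr(m, "zero_columns") <- zc
    out[[hdr[1]]] <- m
  }
  out
}

#' Read the sample sheet
#'
#' Tab-separated with header columns `sample`, `path`, `cohort`, `pair`,
#' `treatment`. Sample ids must be unique; any non-empty pair id must occur
#' in at least two rows.
#'
#' @param path Path to the TSV sample sheet.
#' @return A data.frame with those five character columns.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  ss <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample", "path", "cohort", "pair", "treatment")
  miss <- setdiff(need, names(ss))
  if (length(miss)) stopf("sample sheet lacks column(s): %s",
                          paste(miss, collapse = ", "))
  validate_sample_sheet(ss[, need, drop = FALSE])
}

validate_sample_sheet <- function(ss) {
  if (anyDuplicated(ss$sample))
    stopf("duplicate sample ids: %s",
          paste(unique(ss$sample[duplicated(ss$sample)]), collapse = ", "))
  pr <- ss$pair[!is.na(ss$pair) & nzchar(ss$pair)]
  singles <- names(which(table(pr) < 2))
  if (length(singles)) stopf("pair id(s) with a single member: %s",
                             paste(singles, collapse = ", "))
  ss
}

#' Write a genome store as FASTA
#'
#' @param genome A `genome_store`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    writeLines(paste0(">", nm), con)
    s <- genome$seq[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
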