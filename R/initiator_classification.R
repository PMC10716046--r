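# Strand-aware classification of CAGE 5' ends into YR/YC/OTHER initiator
# classes, 5'TOP subtypes of YC starts, and internal-TOP status.
#
# The initiator dinucleotide is the (-1,+1) base pair around the TSS in
# transcript orientation: YR = pyrimidine then purine (CA, CG, TA, TG),
# YC = pyrimidine then cytosine (CC, TC); everything else is OTHER.
# YC starts are subtyped from the first five transcribed bases:
# 5 pyrimidines (CYYYY) = TOP, 4 of 5 = TOP-deg, otherwise YC-other.

YR_DINUCS <- c("CA", "CG", "TA", "TG")
YC_DINUCS <- c("CC", "TC")

#' Classification parameters
#'
#' @param internal_window Length (bp) of the 5' leader scanned for an
#'   internal TOP element. Default 50.
#' @param internal_run Length of the unbroken pyrimidine run that defines
#'   an internal TOP. Default 5.
#' @param exempt_top_deg If `TRUE`, TOP-deg transcripts are, like 5'TOP
#'   transcripts, not assessed for an internal TOP. Default `FALSE`: only
#'   5'TOP transcripts are exempt.
#' @return A list of class `classification_params`.
#' @export
classification_params <- function(internal_window = 50L, internal_run = 5L,
                                  exempt_top_deg = FALSE) {
  stopifnot(internal_run <= internal_window, internal_run >= 1L)
  structure(list(top_window = 5L,
                 internal_window = as.integer(internal_window),
                 internal_run = as.integer(internal_run),
                 exempt_top_deg = isTRUE(exempt_top_deg)),
            class = "classification_params")
}

#' Initiator dinucleotide at each CTSS
#'
#' Returns the (-1,+1) bases in transcript orientation: on the plus strand
#' these are genome positions `pos - 1` and `pos`; on the minus strand the
#' reverse complements of positions `pos + 1` and `pos`. A CTSS whose
#' upstream base falls off the contig gets `"N"` for that base and is
#' flagged rather than erroring.
#'
#' @param genome A `genome_store`.
#' @param ctss CTSS table with `contig`, `pos`, `strand`.
#' @return A data.frame with columns `minus1`, `plus1`, `flag_edge`.
#' @export
dinucleotide_at <- function(genome, ctss) {
  n <- nrow(ctss)
  minus1 <- plus1 <- rep("N", n)
  flag <- logical(n)
  for (ct in unique(ctss$contig)) {
    if (!ct %in% names(genome$seq)) stopf("CTSS on unknown contig: %s", ct)
    idx <- which(ctss$contig == ct)
    seq <- genome$seq[[ct]]
    len <- genome$lengths[[ct]]
    pos <- ctss$pos[idx]
    if (any(pos < 0 | pos >= len)) stopf("CTSS position outside contig %s", ct)
    plus <- ctss$strand[idx] == "+"
    up <- ifelse(plus, pos - 1L, pos + 1L)
    ok <- up >= 0L & up < len
    flag[idx[!ok]] <- TRUE
    m1 <- rep("N", length(idx))
    if (any(ok)) m1[ok] <- substring(seq, up[ok] + 1L, up[ok] + 1L)
    p1 <- substring(seq, pos + 1L, pos + 1L)
    m1[!plus & ok] <- revcomp(m1[!plus & ok])
    p1[!plus] <- revcomp(p1[!plus])
    minus1[idx] <- m1
    plus1[idx] <- p1
  }
  data.frame(minus1 = minus1, plus1 = plus1, flag_edge = flag,
             stringsAsFactors = FALSE)
}

#' Classify an initiator dinucleotide into YR / YC / OTHER
#'
#' @param minus1,plus1 Character vectors of single bases (transcript
#'   orientation). Any base outside A/C/G/T (including N) gives OTHER.
#' @return Character vector in `{"YR","YC","OTHER"}`.
#' @export
classify_dinucleotide <- function(minus1, plus1) {
  di <- paste0(minus1, plus1)
  out <- rep("OTHER", length(di))
  out[di %in% YR_DINUCS] <- "YR"
  out[di %in% YC_DINUCS] <- "YC"
  out
}

#' First n transcribed bases at each CTSS
#'
#' Transcript-oriented: plus strand reads `[pos, pos + n)`; minus strand
#' reads the reverse complement of `[pos - n + 1, pos + 1)`. Where the
#' contig ends early a shorter string is returned and flagged.
#'
#' @param genome A `genome_store`.
#' @param ctss CTSS table.
#' @param n Number of bases.
#' @return A data.frame with columns `seq` and `flag_short`.
#' @export
first_n_bases <- function(genome, ctss, n) {
  nr <- nrow(ctss)
  out <- character(nr)
  flag <- logical(nr)
  for (ct in unique(ctss$contig)) {
    idx <- which(ctss$contig == ct)
    seq <- genome$seq[[ct]]
    len <- genome$lengths[[ct]]
    pos <- ctss$pos[idx]
    plus <- ctss$strand[idx] == "+"
    from <- ifelse(plus, pos, pmax(pos - n + 1L, 0L))
    to <- ifelse(plus, pmin(pos + n, len), pos + 1L)
    s <- substring(seq, from + 1L, to)
    s[!plus] <- revcomp(s[!plus])
    out[idx] <- s
    flag[idx] <- nchar(s) < n
  }
  data.frame(seq = out, flag_short = flag, stringsAsFactors = FALSE)
}

#' Subtype a YC start from its first five bases
#'
#' Counting the leading C, five pyrimidines (CYYYY) is `TOP`, four of five
#' is `TOP_DEG`, three or fewer is `YC_OTHER`. The first base must be C
#' (the caller guarantees the major class is YC); an N anywhere demotes to
#' `YC_OTHER` with a flag.
#'
#' @param first5 Character vector of length-5 transcript prefixes.
#' @return A data.frame with columns `yc_subtype` and `flag_n`.
#' @export
classify_yc_subtype <- function(first5) {
  if (length(first5) == 0L)
    return(data.frame(yc_subtype = character(0), flag_n = logical(0)))
  lead <- substr(first5, 1L, 1L)
  if (any(lead != "C" & !grepl("N", first5)))
    stopf("classify_yc_subtype called on a non-C start: %s",
          first5[which(lead != "C")[1]])
  has_n <- grepl("N", first5) | nchar(first5) < 5L
  npyr <- vapply(strsplit(substr(first5, 1L, 5L), ""), function(b)
    sum(b %in% PYRIMIDINES), 0L)
  out <- ifelse(npyr == 5L, "TOP", ifelse(npyr == 4L, "TOP_DEG", "YC_OTHER"))
  out[has_n] <- "YC_OTHER"
  data.frame(yc_subtype = out, flag_n = has_n, stringsAsFactors = FALSE)
}

#' Detect an internal TOP element in a 5' leader
#'
#' TRUE when some window of `run` consecutive bases within the leader is
#' all pyrimidine (sliding-window scan).
#'
#' @param leader_seq Character vector of 5' leader sequences (up to the
#'   first `internal_window` transcribed bases).
#' @param run Required unbroken pyrimidine run length. Default 5.
#' @return Logical vector.
#' @export
detect_internal_top <- function(leader_seq, run = 5L) {
  grepl(paste0("[CT]{", run, "}"), leader_seq)
}

#' Classify every CTSS in a table
#'
#' Vectorized driver: initiator dinucleotide, major class, YC subtype and
#' internal-TOP status per row. Internal TOP is assessed within the first
#' `internal_window` transcribed bases for every transcript except 5'TOP
#' transcripts (and TOP-deg when `exempt_top_deg`); it is `NA`
#' (not assessed) for those, and for leaders containing N.
#'
#' @param genome A `genome_store`.
#' @param ctss CTSS table.
#' @param params A [classification_params()] object.
#' @return A data.frame with one row per CTSS: `contig`, `pos`, `strand`,
#'   `dinucleotide`, `major_class`, `yc_subtype` (`NA` unless YC),
#'   `internal_top` (logical, `NA` = not assessed), `flag_edge`.
#' @export
classify_all <- function(genome, ctss, params = classification_params()) {
  if (nrow(ctss) == 0L) {
    return(data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), dinucleotide = character(0),
                      major_class = character(0), yc_subtype = character(0),
                      internal_top = logical(0), flag_edge = logical(0),
                      stringsAsFactors = FALSE))
  }
  di <- dinucleotide_at(genome, ctss)
  major <- classify_dinucleotide(di$minus1, di$plus1)
  major[di$flag_edge] <- "OTHER"

  yc_subtype <- rep(NA_character_, nrow(ctss))
  is_yc <- major == "YC"
  if (any(is_yc)) {
    f5 <- first_n_bases(genome, ctss[is_yc, , drop = FALSE], params$top_window)
    sub5 <- classify_yc_subtype(f5$seq)
    sub5$yc_subtype[f5$flag_short] <- "YC_OTHER"
    yc_subtype[is_yc] <- sub5$yc_subtype
  }

  internal_top <- rep(NA, nrow(ctss))
  exempt <- (major == "YC" & yc_subtype == "TOP") |
    (params$exempt_top_deg & major == "YC" & yc_subtype == "TOP_DEG")
  exempt[is.na(exempt)] <- FALSE
  assess <- !exempt
  if (any(assess)) {
    leaders <- first_n_bases(genome, ctss[assess, , drop = FALSE],
                             params$internal_window)
    val <- detect_internal_top(leaders$seq, params$internal_run)
    val[grepl("N", leaders$seq)] <- NA
    internal_top[assess] <- val
  }

  data.frame(contig = ctss$contig, pos = ctss$pos, strand = ctss$strand,
             dinucleotide = paste0(di$minus1, di$plus1),
             major_class = major, yc_subtype = yc_subtype,
             internal_top = internal_top, flag_edge = di$flag_edge,
             stringsAsFactors = FALSE)
}

#' Write per-CTSS initiator calls as TSV
#'
#' @param calls Output of [classify_all()].
#' @param ctss The matching CTSS table (for per-sample TPM columns).
#' @param path Output path.
#' @export
write_initiator_calls <- function(calls, ctss, path) {
  out <- calls
  for (cl in tpm_cols(ctss)) out[[cl]] <- ctss[[cl]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
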