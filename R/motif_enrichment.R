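# PWM scanning of promoter windows around the dominant CTSS, and Fisher
# enrichment of motif hits in a gene set versus the background of all
# other consensus clusters.

#' Motif scan parameters
#'
#' @param upstream,downstream Window scanned around the dominant CTSS, in
#'   bp before and after it (transcript orientation). Defaults 150 and 50.
#' @param rel_score_threshold Fraction of the PWM min-max score range a
#'   window must reach to count as a hit ("90% match"). Default 0.9.
#' @param pseudocount Total pseudocount distributed over bases per PFM
#'   column. Default 0.8.
#' @param background Base composition (A, C, G, T). Default uniform.
#' @param scan_both_strands Scan the reverse complement too. Default TRUE.
#' @return A list of class `motif_scan_params`.
#' @export
motif_scan_params <- function(upstream = 150L, downstream = 50L,
                              rel_score_threshold = 0.9, pseudocount = 0.8,
                              background = rep(0.25, 4),
                              scan_both_strands = TRUE) {
  stopifnot(rel_score_threshold > 0, rel_score_threshold <= 1,
            abs(sum(background) - 1) < 1e-9, length(background) == 4)
  names(background) <- c("A", "C", "G", "T")
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 rel_score_threshold = rel_score_threshold,
                 pseudocount = pseudocount, background = background,
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "motif_scan_params")
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' `weight[b, i] = log2( (count[b, i] + pseudocount * background[b]) /
#' (colsum_i + pseudocount) / background[b] )`. Per-position minima and
#' maxima are precomputed for relative scoring. A PWM whose min and max
#' coincide (uniform PFM) is degenerate and flagged.
#'
#' @param pfm 4 x width count matrix with rows A, C, G, T.
#' @param pseudocount Total pseudocount per column. Default 0.8.
#' @param background Base frequencies. Default uniform.
#' @return An object of class `pwm`: list with `weights`, `min_score`,
#'   `max_score`, `width`, `id`, `degenerate`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8, background = rep(0.25, 4)) {
  stopifnot(nrow(pfm) == 4)
  names(background) <- c("A", "C", "G", "T")
  rownames(pfm) <- c("A", "C", "G", "T")
  colsum <- colSums(pfm)
  prob <- sweep(pfm + pseudocount * background, 2, colsum + pseudocount, "/")
  w <- log2(prob / background)
  pos_min <- apply(w, 2, min)
  pos_max <- apply(w, 2, max)
  structure(list(weights = w, min_score = sum(pos_min),
                 max_score = sum(pos_max), width = ncol(pfm),
                 id = attr(pfm, "id") %||% "motif",
                 degenerate = sum(pos_max) - sum(pos_min) < 1e-12),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: width %d, score range [%.3f, %.3f]%s\n", x$id, x$width,
              x$min_score, x$max_score,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Relative PWM score of a window
#'
#' `(S - Smin) / (Smax - Smin)` for the summed log-odds score S, in
#' [0, 1]: 1 for the consensus sequence, 0 for the anti-consensus. Windows
#' containing non-ACGT characters score 0.
#'
#' @param window_seq Character vector of sequences of length `pwm$width`.
#' @param pwm A [pfm_to_pwm()] object.
#' @return Numeric vector of fractions.
#' @export
relative_score <- function(window_seq, pwm) {
  if (pwm$degenerate) return(rep(0, length(window_seq)))
  vapply(window_seq, function(s) {
    if (nchar(s) != pwm$width) return(0)
    bi <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(bi)) return(0)
    sc <- sum(pwm$weights[cbind(bi, seq_len(pwm$width))])
    (sc - pwm$min_score) / (pwm$max_score - pwm$min_score)
  }, 0, USE.NAMES = FALSE)
}

# Best relative score over every window of a sequence (one strand).
best_window_score <- function(seq, pwm) {
  w <- pwm$width
  n <- nchar(seq)
  if (n < w || pwm$degenerate) return(list(score = 0, pos = NA_integer_))
  starts <- seq_len(n - w + 1L)
  bi <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  scores <- rep(-Inf, length(starts))
  idx <- matrix(seq_len(w), nrow = length(starts), ncol = w, byrow = TRUE) +
    (starts - 1L)
  valid <- rowSums(matrix(is.na(bi[idx]), nrow = length(starts))) == 0L
  if (any(valid)) {
    wts <- pwm$weights
    sc <- rep(0, sum(valid))
    vidx <- idx[valid, , drop = FALSE]
    for (j in seq_len(w)) sc <- sc + wts[cbind(bi[vidx[, j]], j)]
    scores[valid] <- sc
  }
  rel <- (scores - pwm$min_score) / (pwm$max_score - pwm$min_score)
  rel[!is.finite(rel)] <- 0
  best <- which.max(rel)
  list(score = rel[best], pos = starts[best] - 1L)
}

#' Scan a promoter window around a dominant CTSS for a PWM hit
#'
#' The window runs from `upstream` bp before to `downstream` bp after the
#' dominant CTSS in transcript orientation, truncated (with a flag) at
#' contig edges. Every start position is scored; the promoter is a hit if
#' any window on the forward (or, when enabled, reverse) strand reaches
#' the relative-score threshold. The best position is reported in
#' transcript-oriented coordinates relative to the dominant CTSS.
#'
#' @param genome A `genome_store`.
#' @param contig,pos,strand Dominant CTSS location (0-based).
#' @param pwm A [pfm_to_pwm()] object.
#' @param params A [motif_scan_params()] object.
#' @return A list: `hit`, `best_rel_score`, `best_offset` (bp relative to
#'   the CTSS, negative = upstream), `truncated`.
#' @export
scan_promoter <- function(genome, contig, pos, strand, pwm,
                          params = motif_scan_params()) {
  len <- genome$lengths[[contig]]
  if (strand == "+") {
    from <- pos - params$upstream
    to <- pos + params$downstream + 1L
  } else {
    from <- pos - params$downstream
    to <- pos + params$upstream + 1L
  }
  truncated <- from < 0L || to > len
  cfrom <- max(from, 0L)
  cto <- min(to, len)
  if (cto - cfrom < pwm$width)
    return(list(hit = FALSE, best_rel_score = 0, best_offset = NA_integer_,
                truncated = truncated))
  seq <- genome_fetch(genome, contig, cfrom, cto, strand)
  fwd <- best_window_score(seq, pwm)
  best <- fwd
  if (params$scan_both_strands) {
    rev <- best_window_score(revcomp(seq), pwm)
    if (rev$score > best$score) {
      best <- list(score = rev$score,
                   pos = nchar(seq) - rev$pos - pwm$width)
    }
  }
  # offset of the window start from the CTSS in transcript orientation
  up_avail <- if (strand == "+") pos - cfrom else cto - 1L - pos
  offset <- best$pos - up_avail
  list(hit = best$score >= params$rel_score_threshold,
       best_rel_score = best$score, best_offset = offset,
       truncated = truncated)
}

#' Fisher's exact enrichment of motif hits in a set vs background
#'
#' Two-sided exact test on the 2x2 table of hit/no-hit in the gene set
#' versus the disjoint background, with the sample odds ratio (Haldane
#' +0.5 correction when a cell is zero).
#'
#' @param hits_in_set,size_set Hits and size of the gene set.
#' @param hits_in_background,size_background Hits and size of the
#'   background (all other consensus clusters).
#' @return A list: `odds_ratio`, `p`, `table`, `haldane`.
#' @export
fisher_enrichment <- function(hits_in_set, size_set, hits_in_background,
                              size_background) {
  if (size_set <= 0) stopf("empty gene set")
  tab <- rbind(set = c(hit = hits_in_set, miss = size_set - hits_in_set),
               bg = c(hit = hits_in_background,
                      miss = size_background - hits_in_background))
  if (any(tab < 0)) stopf("hit counts exceed set sizes")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  haldane <- any(tab == 0)
  w <- if (haldane) tab + 0.5 else tab
  or <- (w[1, 1] * w[2, 2]) / (w[1, 2] * w[2, 1])
  list(odds_ratio = or, p = ft$p.value, table = tab, haldane = haldane)
}

#' Motif enrichment over annotated consensus clusters
#'
#' Scans the promoter window of every consensus cluster around its
#' dominant CTSS for each PWM and tests enrichment of hits among the
#' clusters assigned to `set_genes` versus all other consensus clusters.
#'
#' @param genome A `genome_store`.
#' @param consensus Annotated consensus clusters (with `gene_id`).
#' @param dominant Named vector of dominant CTSS positions per cluster id
#'   (from [consensus_expression()]).
#' @param pwms List of [pfm_to_pwm()] objects (or PFMs, converted with
#'   defaults).
#' @param set_genes Character vector of gene ids forming the signature set.
#' @param params A [motif_scan_params()] object.
#' @return A list: `hits` (data.frame cluster x motif hit table),
#'   `enrichment` (data.frame per motif: counts, odds ratio, p).
#' @export
motif_enrichment <- function(genome, consensus, dominant, pwms, set_genes,
                             params = motif_scan_params()) {
  pwms <- lapply(pwms, function(p)
    if (inherits(p, "pwm")) p
    else pfm_to_pwm(p, params$pseudocount, params$background))
  ids <- consensus$id
  in_set <- !is.na(consensus$gene_id) &
    toupper(consensus$gene_id) %in% toupper(set_genes)
  if (!any(in_set)) stopf("no consensus cluster maps to the gene set")
  hit_rows <- list()
  enr <- list()
  for (k in seq_along(pwms)) {
    pwm <- pwms[[k]]
    res <- lapply(seq_along(ids), function(i) {
      p <- dominant[[ids[i]]]
      if (is.na(p)) return(list(hit = FALSE, best_rel_score = 0,
                                best_offset = NA_integer_, truncated = FALSE))
      scan_promoter(genome, consensus$contig[i], p, consensus$strand[i],
                    pwm, params)
    })
    hit <- vapply(res, `[[`, FALSE, "hit")
    hit_rows[[pwm$id]] <- data.frame(
      id = ids, motif = pwm$id, hit = hit,
      best_rel_score = vapply(res, `[[`, 0, "best_rel_score"),
      best_offset = vapply(res, function(r) as.integer(r$best_offset),
                           NA_integer_),
      stringsAsFactors = FALSE)
    fe <- fisher_enrichment(sum(hit[in_set]), sum(in_set),
                            sum(hit[!in_set]), sum(!in_set))
    enr[[pwm$id]] <- data.frame(motif = pwm$id,
                                hits_set = sum(hit[in_set]),
                                size_set = sum(in_set),
                                hits_bg = sum(hit[!in_set]),
                                size_bg = sum(!in_set),
                                odds_ratio = fe$odds_ratio, p = fe$p,
                                stringsAsFactors = FALSE)
  }
  list(hits = do.call(rbind, c(hit_rows, make.row.names = FALSE)),
       enrichment = do.call(rbind, c(enr, make.row.names = FALSE)))
}
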