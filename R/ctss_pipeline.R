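# CTSS-level pipeline: untemplated-G correction, power-law tag-count
# normalization, tag clustering with percentile trimming, cross-sample
# consensus clustering, and promoter annotation.

#' Power-law normalization parameters
#'
#' CAGE tag counts follow an approximate power law; libraries are made
#' comparable by mapping each sample's fitted reverse-cumulative
#' distribution onto a common reference law with slope `-alpha_ref` and
#' total tag count `t_ref`, and the mapped values are reported as TPM.
#'
#' @param alpha_ref Reference power-law slope (dimensionless). Default 1.05.
#' @param t_ref Reference library total. Default 1e6 (so values are tags
#'   per million).
#' @param fit_range Raw-count interval `[low, high]` used for the
#'   least-squares fit. Default `c(5, 1000)`.
#' @return A list of class `normalization_params`.
#' @export
normalization_params <- function(alpha_ref = 1.05, t_ref = 1e6,
                                 fit_range = c(5, 1000)) {
  stopifnot(alpha_ref > 1, t_ref > 0, length(fit_range) == 2,
            fit_range[1] >= 1, fit_range[1] < fit_range[2])
  structure(list(alpha_ref = alpha_ref, t_ref = t_ref, fit_range = fit_range),
            class = "normalization_params")
}

#' Clustering parameters
#'
#' @param ctss_support_tpm Minimum TPM in at least one sample for a CTSS
#'   to enter clustering. Default 0.5.
#' @param max_gap Maximum distance (bp) between neighboring CTSS merged
#'   into one tag cluster. Default 20.
#' @param q_low,q_high Expression percentiles trimming cluster edges.
#'   Default 0.1 and 0.9.
#' @param min_cluster_tpm Cluster expression floor; clusters with TPM
#'   strictly greater are kept. Default 5.
#' @param consensus_dist Maximum gap (bp) between tag clusters aggregated
#'   into one cross-sample consensus cluster. Default 100.
#' @param promoter_window `c(upstream, downstream)` bp around an annotated
#'   TSS defining the promoter region. Default `c(500, 500)`.
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(ctss_support_tpm = 0.5, max_gap = 20L,
                              q_low = 0.1, q_high = 0.9,
                              min_cluster_tpm = 5, consensus_dist = 100L,
                              promoter_window = c(500L, 500L)) {
  stopifnot(q_low >= 0, q_low < q_high, q_high <= 1,
            max_gap >= 1, consensus_dist >= 1,
            length(promoter_window) == 2, all(promoter_window >= 0))
  structure(list(ctss_support_tpm = ctss_support_tpm,
                 max_gap = as.integer(max_gap),
                 q_low = q_low, q_high = q_high,
                 min_cluster_tpm = min_cluster_tpm,
                 consensus_dist = as.integer(consensus_dist),
                 promoter_window = as.integer(promoter_window)),
            class = "clustering_params")
}

#' Remove the untemplated CAGE G
#'
#' The CAGE protocol adds an extra G at read 5' ends. Rows whose observed
#' first base (column `first_base`) is G while the genome base at their
#' position (strand-oriented) is not G are shifted one base in the
#' transcript 3' direction; counts are then re-aggregated by position.
#' Rows shifted beyond the contig are dropped with a warning.
#'
#' @param ctss CTSS table carrying a `first_base` column with the observed
#'   first base of the reads at that position.
#' @param genome A `genome_store`.
#' @return The corrected CTSS table (without `first_base`).
#' @export
correct_extra_g <- function(ctss, genome) {
  if (is.null(ctss$first_base))
    stopf("correct_extra_g needs a `first_base` column")
  gbase <- character(nrow(ctss))
  for (ct in unique(ctss$contig)) {
    idx <- which(ctss$contig == ct)
    b <- substring(genome$seq[[ct]], ctss$pos[idx] + 1L, ctss$pos[idx] + 1L)
    neg <- ctss$strand[idx] == "-"
    b[neg] <- revcomp(b[neg])
    gbase[idx] <- b
  }
  shift <- ctss$first_base == "G" & gbase != "G"
  newpos <- ctss$pos + ifelse(ctss$strand == "+", 1L, -1L) * as.integer(shift)
  len <- genome$lengths[ctss$contig]
  off <- newpos < 0L | newpos >= len
  if (any(off)) {
    warnf("G-correction dropped %d row(s) shifted beyond a contig end", sum(off))
  }
  out <- ctss[!off, , drop = FALSE]
  out$pos <- newpos[!off]
  out$first_base <- NULL
  # re-aggregate counts at coinciding corrected positions
  key <- paste(out$contig, out$pos, out$strand, sep = "\r")
  if (anyDuplicated(key)) {
    ccols <- count_cols(out)
    agg <- stats::aggregate(out[ccols], by = list(.key = key), FUN = sum)
    first <- out[!duplicated(key), c("contig", "pos", "strand"), drop = FALSE]
    first <- first[match(agg$.key, unique(key)), , drop = FALSE]
    out <- cbind(first, agg[ccols])
  }
  order_ctss(out)
}

# Least-squares fit of the reverse-cumulative count distribution in
# log10-log10 space over distinct counts within fit_range.
# Returns list(alpha, x0, ok).
fit_power_law <- function(counts, fit_range) {
  counts <- counts[counts > 0]
  v <- sort(unique(counts))
  v <- v[v >= fit_range[1] & v <= fit_range[2]]
  if (length(v) < 2L) return(list(alpha = NA_real_, x0 = NA_real_, ok = FALSE))
  num <- vapply(v, function(x) sum(counts >= x), 0)
  lx <- log10(v)
  ly <- log10(num)
  if (stats::var(lx) == 0) return(list(alpha = NA_real_, x0 = NA_real_, ok = FALSE))
  fit <- stats::lm.fit(cbind(1, lx), ly)
  b <- fit$coefficients[1]
  a <- -fit$coefficients[2]
  if (!is.finite(a) || a <= 0) return(list(alpha = NA_real_, x0 = NA_real_, ok = FALSE))
  list(alpha = a, x0 = 10^(b / a), ok = TRUE)
}

# Count at which the reference law of slope -alpha reaches rank 1, chosen
# so that the law's total tag count is t_ref (continuous Pareto total).
reference_x0 <- function(alpha_ref, t_ref) {
  total <- function(x0) alpha_ref / (alpha_ref - 1) * x0^alpha_ref *
    (1 - x0^(1 - alpha_ref)) - t_ref
  stats::uniroot(total, lower = 1 + 1e-9, upper = 1e15, tol = 1e-9)$root
}

#' Power-law normalization of raw tag counts
#'
#' Per sample, the reverse-cumulative rank of counts is fitted against the
#' count in log10-log10 space by least squares over `fit_range`, giving a
#' sample law with slope `-a_s` reaching rank 1 at count `x0_s`. Each raw
#' count c is mapped onto the reference law (slope `-alpha_ref`, total
#' `t_ref`) as `c' = (c / x0_s)^(a_s / alpha_ref) * x0_r`, a strictly
#' increasing mapping reported as TPM. Samples whose fit is infeasible
#' (fewer than two distinct counts in range, or a degenerate fit) fall
#' back to [simple_tpm()] with a warning.
#'
#' @param ctss Multi- or single-sample CTSS table with `count.*` columns.
#' @param params A [normalization_params()] object.
#' @return The table with `tpm.*` columns filled.
#' @export
power_law_normalize <- function(ctss, params = normalization_params()) {
  x0_r <- reference_x0(params$alpha_ref, params$t_ref)
  for (s in ctss_samples(ctss)) {
    cnt <- ctss[[paste0("count.", s)]]
    fit <- fit_power_law(cnt, params$fit_range)
    if (!fit$ok) {
      warnf("sample %s: power-law fit infeasible; falling back to simple TPM", s)
      ctss[[paste0("tpm.", s)]] <- cnt / sum(cnt) * 1e6
      next
    }
    tpm <- numeric(length(cnt))
    pos <- cnt > 0
    tpm[pos] <- (cnt[pos] / fit$x0)^(fit$alpha / params$alpha_ref) * x0_r
    ctss[[paste0("tpm.", s)]] <- tpm
  }
  ctss
}

#' Plain tags-per-million normalization
#'
#' Fallback scaling `tpm = count / total * 1e6`; per-sample TPM sums to
#' exactly 1e6.
#'
#' @param ctss CTSS table with `count.*` columns.
#' @return The table with `tpm.*` columns filled.
#' @export
simple_tpm <- function(ctss) {
  for (s in ctss_samples(ctss)) {
    cnt <- ctss[[paste0("count.", s)]]
    tot <- sum(cnt)
    if (tot <= 0) stopf("sample %s has zero total count", s)
    ctss[[paste0("tpm.", s)]] <- cnt / tot * 1e6
  }
  ctss
}

#' Cluster supported CTSS into tag clusters
#'
#' CTSS with at least `ctss_support_tpm` TPM in one of the samples (of
#' `samples`, default all) are clustered per (contig, strand) into maximal
#' runs in which consecutive CTSS are at most `max_gap` bp apart. Cluster
#' expression is the pooled TPM over `samples`.
#'
#' @param ctss Normalized CTSS table.
#' @param params A [clustering_params()] object.
#' @param samples Samples whose TPM is pooled for cluster expression;
#'   default all samples in the table.
#' @return A data.frame of class `tag_clusters` with columns `cluster`,
#'   `contig`, `strand`, `start`, `end` (raw span, half-open), `tstart`,
#'   `tend` (trimmed span, initially the raw span), `tpm`, `dominant_pos`,
#'   `n_ctss`; the supported CTSS with their cluster assignment are
#'   attached as attribute `"ctss"`.
#' @export
cluster_ctss <- function(ctss, params = clustering_params(), samples = NULL) {
  tpm <- ctss_tpm_matrix(ctss, samples)
  if (ncol(tpm) == 0L) stopf("no tpm.* columns; normalize first")
  support <- apply(tpm, 1, max) >= params$ctss_support_tpm
  x <- ctss[support, c("contig", "pos", "strand"), drop = FALSE]
  x$tpm_pooled <- rowSums(tpm[support, , drop = FALSE])
  x <- x[order(x$contig, x$strand, x$pos), , drop = FALSE]
  if (nrow(x) == 0L) {
    return(empty_tag_clusters(x))
  }
  grp <- paste(x$contig, x$strand, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-nrow(x)])
  gap <- c(0L, diff(x$pos))
  x$cluster <- cumsum(new_grp | gap > params$max_gap)
  summarize_tag_clusters(x)
}

empty_tag_clusters <- function(x) {
  out <- data.frame(cluster = integer(0), contig = character(0),
                    strand = character(0), start = integer(0), end = integer(0),
                    tstart = integer(0), tend = integer(0), tpm = numeric(0),
                    dominant_pos = integer(0), n_ctss = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "ctss") <- x
  class(out) <- c("tag_clusters", "data.frame")
  out
}

# Build the cluster summary table from member CTSS (column `cluster`).
summarize_tag_clusters <- function(x) {
  sp <- split(seq_len(nrow(x)), x$cluster)
  rows <- lapply(sp, function(ii) {
    m <- x[ii, , drop = FALSE]
    dom <- dominant_position(m$pos, m$tpm_pooled, m$strand[1])
    data.frame(cluster = m$cluster[1], contig = m$contig[1],
               strand = m$strand[1],
               start = min(m$pos), end = max(m$pos) + 1L,
               tstart = min(m$pos), tend = max(m$pos) + 1L,
               tpm = sum(m$tpm_pooled), dominant_pos = dom,
               n_ctss = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ctss") <- x
  class(out) <- c("tag_clusters", "data.frame")
  out
}

# Highest-expressed position; ties resolve 5'-most in transcript
# orientation (smallest position on +, largest on -).
dominant_position <- function(pos, tpm, strand) {
  best <- which(tpm == max(tpm))
  if (strand == "+") pos[best[1]] else pos[best[length(best)]]
}

#' Trim tag clusters to expression percentiles
#'
#' Edges are trimmed to the positions of the `q_low` and `q_high`
#' percentiles of expression: `tstart` is the smallest member position
#' whose left-inclusive cumulative TPM reaches `q_low * total`, and the
#' trimmed end is the smallest position whose cumulative TPM reaches
#' `q_high * total`. The retained mass is therefore at least
#' `(q_high - q_low) * total`. Cluster TPM and the dominant position are
#' recomputed over the trimmed span (the raw span and mass are kept in
#' `start`/`end`).
#'
#' @param clusters A `tag_clusters` object.
#' @param q_low,q_high Trimming percentiles.
#' @return The `tag_clusters` object with `tstart`, `tend`, `tpm`,
#'   `dominant_pos` updated.
#' @export
trim_clusters <- function(clusters, q_low = 0.1, q_high = 0.9) {
  x <- attr(clusters, "ctss")
  sp <- split(seq_len(nrow(x)), x$cluster)
  for (i in seq_len(nrow(clusters))) {
    ii <- sp[[as.character(clusters$cluster[i])]]
    m <- x[ii, , drop = FALSE]
    m <- m[order(m$pos), , drop = FALSE]
    total <- sum(m$tpm_pooled)
    cum <- cumsum(m$tpm_pooled)
    lo <- which(cum >= q_low * total)[1]
    hi <- which(cum >= q_high * total)[1]
    keep <- seq(lo, hi)
    clusters$tstart[i] <- m$pos[lo]
    clusters$tend[i] <- m$pos[hi] + 1L
    clusters$tpm[i] <- sum(m$tpm_pooled[keep])
    clusters$dominant_pos[i] <- dominant_position(m$pos[keep],
                                                  m$tpm_pooled[keep],
                                                  m$strand[1])
  }
  clusters
}

#' Filter tag clusters on expression
#'
#' Retains clusters whose (trimmed) TPM is strictly greater than
#' `min_cluster_tpm`.
#'
#' @param clusters A `tag_clusters` object.
#' @param min_cluster_tpm Expression floor (strict). Default 5.
#' @return The filtered `tag_clusters` object.
#' @export
filter_clusters <- function(clusters, min_cluster_tpm = 5) {
  keep <- clusters$tpm > min_cluster_tpm
  out <- clusters[keep, , drop = FALSE]
  x <- attr(clusters, "ctss")
  attr(out, "ctss") <- x[x$cluster %in% out$cluster, , drop = FALSE]
  class(out) <- c("tag_clusters", "data.frame")
  out
}

#' Aggregate tag clusters into cross-sample consensus clusters
#'
#' Single-linkage merge of trimmed cluster spans per (contig, strand):
#' clusters whose spans are within `consensus_dist` bp of each other (gap
#' between span end and next span start) join one consensus cluster whose
#' span is the union envelope. Stable ids are assigned in (contig, start,
#' strand) order. Re-aggregating the output changes nothing.
#'
#' @param clusters A `tag_clusters` object, a list of them (one per
#'   sample), or any data.frame with `contig`, `strand` and either
#'   `tstart`/`tend` or `start`/`end` spans.
#' @param consensus_dist Maximum inter-span gap (bp). Default 100.
#' @return A data.frame of class `consensus_clusters`: `id`, `contig`,
#'   `strand`, `start`, `end`, `n_members`; member spans are attached as
#'   attribute `"members"`.
#' @export
aggregate_consensus <- function(clusters, consensus_dist = 100L) {
  if (inherits(clusters, "data.frame")) clusters <- list(clusters)
  spans <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    s <- if (!is.null(cl$tstart)) cl$tstart else cl$start
    e <- if (!is.null(cl$tend)) cl$tend else cl$end
    data.frame(member = i, contig = cl$contig, strand = cl$strand,
               start = s, end = e, stringsAsFactors = FALSE)
  }))
  if (is.null(spans) || nrow(spans) == 0L) {
    out <- data.frame(id = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "members") <- spans
    class(out) <- c("consensus_clusters", "data.frame")
    return(out)
  }
  spans <- spans[order(spans$contig, spans$strand, spans$start, spans$end), ,
                 drop = FALSE]
  grp <- paste(spans$contig, spans$strand, sep = "\r")
  n <- nrow(spans)
  cummax_end <- spans$end
  comp <- integer(n)
  comp[1] <- 1L
  for (i in seq_len(n)[-1]) {
    if (grp[i] != grp[i - 1] ||
        spans$start[i] - cummax_end[i - 1] > consensus_dist) {
      comp[i] <- comp[i - 1] + 1L
      cummax_end[i] <- spans$end[i]
    } else {
      comp[i] <- comp[i - 1]
      cummax_end[i] <- max(cummax_end[i - 1], spans$end[i])
    }
  }
  spans$consensus <- comp
  sp <- split(seq_len(n), comp)
  rows <- lapply(sp, function(ii) {
    m <- spans[ii, , drop = FALSE]
    data.frame(contig = m$contig[1], strand = m$strand[1],
               start = min(m$start), end = max(m$end),
               n_members = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$contig, out$start, out$strand)
  out <- out[ord, , drop = FALSE]
  out$id <- sprintf("CC%05d", seq_len(nrow(out)))
  out <- out[, c("id", "contig", "strand", "start", "end", "n_members")]
  rownames(out) <- NULL
  remap <- stats::setNames(out$id, as.character(as.integer(names(sp)))[ord])
  spans$consensus <- remap[as.character(spans$consensus)]
  attr(out, "members") <- spans
  class(out) <- c("consensus_clusters", "data.frame")
  out
}

#' Per-consensus-cluster expression by sample and initiator class
#'
#' Assigns every CTSS falling inside a consensus span (same contig and
#' strand) to that cluster and sums TPM per sample, in total and per
#' initiator class when calls are supplied. The per-class TPM of a cluster
#' sums to its total TPM.
#'
#' @param consensus A `consensus_clusters` object.
#' @param ctss Normalized CTSS table.
#' @param calls Optional [classify_all()] output matching `ctss` rows.
#' @return A list with elements `tpm` (clusters x samples matrix),
#'   `class_tpm` (named list of matrices for YR, YC, OTHER and, when
#'   available, TOP, TOP_DEG, YC_OTHER), `dominant` (named vector of
#'   dominant CTSS positions) and `assignment` (consensus id per CTSS row,
#'   NA outside all clusters).
#' @export
consensus_expression <- function(consensus, ctss, calls = NULL) {
  tpm <- ctss_tpm_matrix(ctss)
  assignment <- rep(NA_character_, nrow(ctss))
  for (key in unique(paste(consensus$contig, consensus$strand, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ci <- which(consensus$contig == parts[1] & consensus$strand == parts[2])
    ri <- which(ctss$contig == parts[1] & ctss$strand == parts[2])
    if (!length(ci) || !length(ri)) next
    ord <- ci[order(consensus$start[ci])]
    idx <- findInterval(ctss$pos[ri], consensus$start[ord])
    ok <- idx >= 1 & idx <= length(ord)
    ok[ok] <- ctss$pos[ri][ok] < consensus$end[ord][idx[ok]]
    assignment[ri[ok]] <- consensus$id[ord][idx[ok]]
  }
  ids <- consensus$id
  sum_by <- function(rows) {
    m <- matrix(0, nrow = length(ids), ncol = ncol(tpm),
                dimnames = list(ids, colnames(tpm)))
    if (length(rows)) {
      agg <- rowsum(tpm[rows, , drop = FALSE], group = assignment[rows])
      m[rownames(agg), ] <- agg
    }
    m
  }
  inside <- which(!is.na(assignment))
  total <- sum_by(inside)
  class_tpm <- NULL
  if (!is.null(calls)) {
    class_tpm <- list()
    for (cls in c("YR", "YC", "OTHER")) {
      class_tpm[[cls]] <- sum_by(inside[calls$major_class[inside] == cls])
    }
    for (sub in c("TOP", "TOP_DEG", "YC_OTHER")) {
      rows <- inside[!is.na(calls$yc_subtype[inside]) &
                       calls$yc_subtype[inside] == sub]
      class_tpm[[sub]] <- sum_by(rows)
    }
  }
  dominant <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  pooled <- rowSums(tpm)
  for (id in ids) {
    rows <- which(assignment == id)
    if (length(rows)) {
      strand <- consensus$strand[consensus$id == id]
      dominant[id] <- dominant_position(ctss$pos[rows], pooled[rows], strand)
    }
  }
  list(tpm = total, class_tpm = class_tpm, dominant = dominant,
       assignment = assignment)
}

#' Assign consensus clusters to gene promoters
#'
#' A consensus cluster is assigned to a gene when its span overlaps the
#' promoter window `[TSS - upstream, TSS + downstream]` on the same strand.
#' Where windows of several genes overlap, the gene with the nearest TSS
#' wins; exact distance ties go to the lexicographically smaller gene id.
#' Clusters overlapping no window get `NA` (non-promoter).
#'
#' @param consensus A `consensus_clusters` object.
#' @param genes Gene models from [read_gtf_genes()].
#' @param promoter_window `c(upstream, downstream)` bp. Default
#'   `c(500, 500)`.
#' @return The consensus table with columns `gene_id` and `tss_dist` added.
#' @export
annotate_promoters <- function(consensus, genes, promoter_window = c(500L, 500L)) {
  up <- promoter_window[1]
  down <- promoter_window[2]
  gene_id <- rep(NA_character_, nrow(consensus))
  tss_dist <- rep(NA_integer_, nrow(consensus))
  for (i in seq_len(nrow(consensus))) {
    g <- genes[genes$contig == consensus$contig[i] &
                 genes$strand == consensus$strand[i], , drop = FALSE]
    if (!nrow(g)) next
    wstart <- g$tss - up
    wend <- g$tss + down + 1L  # half-open
    hit <- consensus$start[i] < wend & consensus$end[i] > wstart
    if (!any(hit)) next
    g <- g[hit, , drop = FALSE]
    d <- pmax(0L, consensus$start[i] - g$tss, g$tss - (consensus$end[i] - 1L))
    best <- order(d, g$gene_id)[1]
    gene_id[i] <- g$gene_id[best]
    tss_dist[i] <- d[best]
  }
  consensus$gene_id <- gene_id
  consensus$tss_dist <- tss_dist
  consensus
}

#' Merge consensus-cluster expression to gene level
#'
#' Where several consensus clusters map to one gene, their TPM values are
#' summed, per sample and per class. Non-promoter clusters (no gene) are
#' excluded.
#'
#' @param consensus Annotated consensus clusters (with `gene_id`).
#' @param expr Output of [consensus_expression()].
#' @return A list with `tpm` and `class_tpm` matrices with gene rownames.
#' @export
gene_level_expression <- function(consensus, expr) {
  keep <- !is.na(consensus$gene_id)
  grp <- consensus$gene_id[keep]
  merge_m <- function(m) rowsum(m[consensus$id[keep], , drop = FALSE], group = grp)
  out <- list(tpm = merge_m(expr$tpm))
  if (!is.null(expr$class_tpm)) out$class_tpm <- lapply(expr$class_tpm, merge_m)
  out
}

#' Write tag or consensus clusters as BED
#'
#' BED12-flavored: thickStart/thickEnd carry the trimmed span for tag
#' clusters (for consensus clusters they repeat the span).
#'
#' @param clusters A `tag_clusters` or `consensus_clusters` object.
#' @param path Output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  name <- if (!is.null(clusters$id)) clusters$id else
    sprintf("TC%05d", clusters$cluster)
  score <- if (!is.null(clusters$tpm)) pmin(1000L, as.integer(round(clusters$tpm)))
    else 0L
  ts <- if (!is.null(clusters$tstart)) clusters$tstart else clusters$start
  te <- if (!is.null(clusters$tend)) clusters$tend else clusters$end
  x <- data.frame(clusters$contig, clusters$start, clusters$end, name, score,
                  clusters$strand, ts, te)
  x <- x[order(clusters$contig, clusters$start, clusters$strand), , drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
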