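# End-to-end orchestration: normalization -> per-sample tag clustering ->
# trimming -> expression filter -> cross-sample consensus -> promoter
# annotation -> initiator classification -> DIP calling -> YC:YR ratios,
# with a classed result object and a plain-text run report.

#' Run the dual-initiation promoter pipeline
#'
#' Executes the full analysis on a multi-sample CTSS table: power-law
#' normalization (optional untemplated-G correction first), per-sample tag
#' clustering with percentile trimming, the cluster expression filter
#' (pooled across samples by default), consensus aggregation, promoter
#' annotation, per-CTSS initiator classification, gene-level class
#' expression, DIP calling and YC:YR ratios.
#'
#' @param ctss A multi-sample CTSS table (see [merge_ctss()]) or a list of
#'   single-sample tables.
#' @param genome A `genome_store`.
#' @param genes Gene models from [read_gtf_genes()] (or the synthetic
#'   generator).
#' @param norm [normalization_params()].
#' @param clust [clustering_params()].
#' @param classp [classification_params()].
#' @param dipp [dip_params()].
#' @param g_correct Apply [correct_extra_g()] first (requires a
#'   `first_base` column). Default FALSE: input positions are taken as
#'   already corrected CTSS.
#' @param filter_mode `"pooled"` applies the cluster expression floor to
#'   the pooled TPM across samples (default); `"per_sample"` to each
#'   sample's own cluster TPM.
#' @return An object of class `dip_run`: a list with elements `ctss`
#'   (normalized table), `clusters` (per-sample `tag_clusters`),
#'   `consensus` (annotated), `calls`, `expr` (consensus expression),
#'   `gene` (gene-level `tpm` and `class_tpm`), `dips`, `ratios`,
#'   `class_totals` (per-sample YR/YC/OTHER TPM totals over consensus
#'   clusters), `params`, `log`.
#' @export
run_pipeline <- function(ctss, genome, genes,
                         norm = normalization_params(),
                         clust = clustering_params(),
                         classp = classification_params(),
                         dipp = dip_params(),
                         g_correct = FALSE,
                         filter_mode = c("pooled", "per_sample")) {
  filter_mode <- match.arg(filter_mode)
  if (is.list(ctss) && !is.data.frame(ctss)) ctss <- merge_ctss(ctss)
  log <- c(sprintf("input: %d CTSS, %d sample(s)", nrow(ctss),
                   length(ctss_samples(ctss))))
  if (g_correct) {
    ctss <- correct_extra_g(ctss, genome)
    log <- c(log, sprintf("g_correction: %d CTSS after re-aggregation",
                          nrow(ctss)))
  }
  ctss <- power_law_normalize(ctss, norm)
  samples <- ctss_samples(ctss)

  clusters <- list()
  for (s in samples) {
    cl <- cluster_ctss(ctss, clust, samples = s)
    cl <- trim_clusters(cl, clust$q_low, clust$q_high)
    if (filter_mode == "per_sample") {
      cl <- filter_clusters(cl, clust$min_cluster_tpm)
    } else {
      pooled <- cluster_pooled_tpm(cl, ctss)
      keep <- pooled > clust$min_cluster_tpm
      x <- attr(cl, "ctss")
      cl <- cl[keep, , drop = FALSE]
      attr(cl, "ctss") <- x[x$cluster %in% cl$cluster, , drop = FALSE]
      class(cl) <- c("tag_clusters", "data.frame")
    }
    clusters[[s]] <- cl
    log <- c(log, sprintf("sample %s: %d tag clusters after trim+filter",
                          s, nrow(cl)))
  }

  consensus <- aggregate_consensus(clusters, clust$consensus_dist)
  log <- c(log, sprintf("consensus: %d clusters", nrow(consensus)))
  calls <- classify_all(genome, ctss, classp)
  expr <- consensus_expression(consensus, ctss, calls)
  consensus <- annotate_promoters(consensus, genes, clust$promoter_window)
  log <- c(log, sprintf("annotation: %d of %d consensus clusters at promoters",
                        sum(!is.na(consensus$gene_id)), nrow(consensus)))
  gene <- gene_level_expression(consensus, expr)
  dips <- call_dips(gene$class_tpm$YC, gene$class_tpm$YR, dipp)
  log <- c(log, sprintf("dips: %d of %d genes", sum(dips), length(dips)))
  dip_genes <- names(dips)[dips]
  ratios <- yc_yr_ratio(gene$class_tpm$YC[dip_genes, , drop = FALSE],
                        gene$class_tpm$YR[dip_genes, , drop = FALSE],
                        dipp$pseudocount)
  class_totals <- sapply(expr$class_tpm[c("YR", "YC", "OTHER")], colSums)

  structure(list(ctss = ctss, clusters = clusters, consensus = consensus,
                 calls = calls, expr = expr, gene = gene, dips = dips,
                 ratios = ratios, class_totals = class_totals,
                 params = list(norm = norm, clust = clust, classp = classp,
                               dipp = dipp, filter_mode = filter_mode),
                 log = log),
            class = "dip_run")
}

# Pooled (all samples) TPM of each cluster's trimmed span.
cluster_pooled_tpm <- function(clusters, ctss) {
  tpm <- rowSums(ctss_tpm_matrix(ctss))
  out <- numeric(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    rows <- ctss$contig == clusters$contig[i] &
      ctss$strand == clusters$strand[i] &
      ctss$pos >= clusters$tstart[i] & ctss$pos < clusters$tend[i]
    out[i] <- sum(tpm[rows])
  }
  out
}

#' @export
print.dip_run <- function(x, ...) {
  cat("dip_run:", length(ctss_samples(x$ctss)), "sample(s),",
      nrow(x$ctss), "CTSS\n")
  cat("  consensus clusters:", nrow(x$consensus),
      sprintf("(%d at promoters)", sum(!is.na(x$consensus$gene_id))), "\n")
  cat("  genes quantified:", nrow(x$gene$tpm), "\n")
  cat("  dual-initiation promoters:", sum(x$dips), "\n")
  invisible(x)
}

#' @export
summary.dip_run <- function(object, ...) {
  tot <- object$class_totals
  frac_yc <- tot[, "YC"] / (tot[, "YC"] + tot[, "YR"])
  out <- list(n_ctss = nrow(object$ctss),
              n_consensus = nrow(object$consensus),
              n_genes = nrow(object$gene$tpm),
              n_dips = sum(object$dips),
              class_totals = tot,
              yc_content = frac_yc)
  class(out) <- "summary.dip_run"
  out
}

#' @export
print.summary.dip_run <- function(x, ...) {
  cat("Pipeline summary\n")
  cat(sprintf("  CTSS: %d   consensus clusters: %d   genes: %d   DIPs: %d\n",
              x$n_ctss, x$n_consensus, x$n_genes, x$n_dips))
  cat("  per-sample YC content of consensus-cluster expression:\n")
  for (s in names(x$yc_content))
    cat(sprintf("    %-24s %5.1f%%\n", s, 100 * x$yc_content[s]))
  invisible(x)
}

#' Write the run report and intermediate tables
#'
#' Emits `report.txt` (stage log and figure-level summaries), plus
#' `consensus_clusters.bed`, `class_tpm.tsv` (consensus id x sample x
#' class), `gene_class_tpm.tsv`, `dips.tsv` and `ratios.tsv`. Every number
#' in the report is computed from those tables.
#'
#' @param run A `dip_run` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_clusters_bed(run$consensus, file.path(dir, "consensus_clusters.bed"))
  long <- do.call(rbind, lapply(names(run$expr$class_tpm), function(cls) {
    m <- run$expr$class_tpm[[cls]]
    data.frame(id = rep(rownames(m), ncol(m)),
               sample = rep(colnames(m), each = nrow(m)),
               class = cls, tpm = as.vector(m), stringsAsFactors = FALSE)
  }))
  utils::write.table(long, file.path(dir, "class_tpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gm <- do.call(cbind, lapply(names(run$gene$class_tpm), function(cls) {
    m <- run$gene$class_tpm[[cls]]
    colnames(m) <- paste(cls, colnames(m), sep = ".")
    m
  }))
  utils::write.table(data.frame(gene_id = rownames(gm), gm,
                                check.names = FALSE),
                     file.path(dir, "gene_class_tpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(run$dips), dip = run$dips),
                     file.path(dir, "dips.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(run$ratios$r),
                                run$ratios$r, check.names = FALSE),
                     file.path(dir, "ratios.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rep <- c("dual-initiation promoter pipeline report", "", run$log, "",
           "per-sample class totals (TPM over consensus clusters):",
           utils::capture.output(print(round(run$class_totals, 1))), "",
           utils::capture.output(print(summary(run))))
  writeLines(rep, file.path(dir, "report.txt"))
  invisible(dir)
}
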