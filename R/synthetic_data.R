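# Synthetic CAGE-like data with known ground truth: a genome whose
# promoters carry engineered YR/YC initiator contexts (with 5'TOP,
# TOP-deg and YC-other 5-mers), gene models, and multi-sample CTSS tag
# tables whose counts follow a discrete power law, with cohort-dependent
# YC fractions, optional irradiation effects, intergenic noise, and
# motif-bearing signature promoters.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Synthetic data configuration
#'
#' Defaults define the standard simulation: 1,000 promoters over two
#' contigs, three cohorts (responsive > moderate > non-responsive) of two
#' samples each, one million tags per sample. Cohort YC-fraction Beta
#' means of 0.35 / 0.25 / 0.15 echo the observed organoid range (about a
#' third of transcripts starting with C in the most radiotherapy-
#' responsive samples down to 15% in the least responsive); irradiation
#' multiplies YC mass by 0.55 / 0.716 / 0.951 per cohort (45%, 28.4% and
#' 4.9% depletion).
#'
#' @param seed RNG seed; identical seeds reproduce outputs exactly.
#' @param n_promoters Number of promoters. Default 1000.
#' @param n_contigs Contigs the promoters are spread over. Default 2.
#' @param spacing Distance between promoter cores (bp). Default 1000.
#' @param cohorts Cohort labels, ordered from highest to lowest expected
#'   YC fraction.
#' @param samples_per_cohort Samples per cohort. Default 2.
#' @param yc_mean Named per-cohort mean of the Beta distribution of
#'   per-promoter YC fractions.
#' @param yc_concentration Beta concentration (a + b). Default 10.
#' @param dip_fraction Fraction of promoters that are dual-initiating;
#'   the rest emit only YR tags. Default 0.7.
#' @param trajectory_fraction Fraction of dual promoters planted with a
#'   strictly ordered cohort effect. Default 0.1.
#' @param trajectory_delta Logit offset of the planted cohort trajectory.
#'   Default 1.2.
#' @param tag_exponent Power-law exponent of promoter tag weights.
#'   Default 1.05.
#' @param weight_cap Upper truncation of the Pareto weights (finite
#'   library dynamic range). Default 1e4.
#' @param depth Tags per sample. Default 1e6.
#' @param noise_rate Intergenic noise tags per kb of genome. Default 2.
#' @param treatment If TRUE, each sample gets a matched control and
#'   irradiated library.
#' @param treatment_effect Named per-cohort multiplier of YC mass upon
#'   irradiation.
#' @param top_fraction Probabilities of the YC 5-mer subtypes.
#' @param motif_consensus Motif planted into signature promoters.
#' @param motif_rate Named plant rates for signature (trajectory) and
#'   background promoters.
#' @param motif_offset Transcript-oriented offset of the planted motif
#'   from the promoter TSS. Default -60.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L,
                             n_promoters = 1000L,
                             n_contigs = 2L,
                             spacing = 1000L,
                             cohorts = c("responsive", "moderate", "non_responsive"),
                             samples_per_cohort = 2L,
                             yc_mean = c(responsive = 0.35, moderate = 0.25,
                                         non_responsive = 0.15),
                             yc_concentration = 10,
                             dip_fraction = 0.7,
                             trajectory_fraction = 0.1,
                             trajectory_delta = 1.2,
                             tag_exponent = 1.05,
                             weight_cap = 1e4,
                             depth = 1e6,
                             noise_rate = 2,
                             treatment = FALSE,
                             treatment_effect = c(responsive = 0.55,
                                                  moderate = 0.716,
                                                  non_responsive = 0.951),
                             top_fraction = c(TOP = 0.25, TOP_DEG = 0.25,
                                              YC_OTHER = 0.5),
                             motif_consensus = "CCGGAAGT",
                             motif_rate = c(signature = 0.3, background = 0.1),
                             motif_offset = -60L) {
  stopifnot(all(cohorts %in% names(yc_mean)),
            all(yc_mean > 0 & yc_mean < 1),
            dip_fraction >= 0, dip_fraction <= 1,
            trajectory_fraction >= 0, trajectory_fraction <= 1,
            tag_exponent > 1, depth > 0,
            abs(sum(top_fraction) - 1) < 1e-9)
  structure(as.list(environment()), class = "synthetic_config")
}

# Draw a pyrimidine-pattern 5-mer for a YC start of the given subtype.
draw_yc_pentamer <- function(subtype) {
  pyr <- function(n) sample(PYRIMIDINES, n, replace = TRUE)
  pur <- function(n) sample(PURINES, n, replace = TRUE)
  tail4 <- switch(subtype,
    TOP = pyr(4),
    TOP_DEG = {
      b <- pyr(4)
      b[sample.int(4, 1)] <- pur(1)
      b
    },
    YC_OTHER = {
      b <- pyr(4)
      b[sample.int(4, 2)] <- pur(2)
      b
    })
  paste0("C", paste(tail4, collapse = ""))
}

# Write a transcript-oriented initiator context into a contig base vector.
# p is the 0-based CTSS position; minus1 the -1 base; first_k the +1..+k
# bases, all transcript-oriented.
write_context <- function(vec, p, strand, minus1, first_k) {
  fb <- strsplit(first_k, "")[[1]]
  if (strand == "+") {
    vec[p] <- minus1                 # 1-based index p = genomic p-1
    vec[p + seq_along(fb)] <- fb
  } else {
    vec[p + 2L] <- COMP[[minus1]]
    vec[p + 2L - seq_along(fb)] <- COMP[fb]
  }
  vec
}

#' Generate a synthetic genome, annotation and promoter registry
#'
#' Promoters are placed non-overlapping on alternating contigs and
#' strands. Each promoter carries four CTSS in an 18-bp core (two YC
#' followed, in transcript direction, by two YR; YR-only promoters carry
#' four YR CTSS); the local sequence is rewritten so each designated CTSS
#' sits on its intended initiator context, YC CTSS on the configured
#' TOP / TOP-deg / YC-other 5-mer. The motif consensus is written into
#' planted promoters at `motif_offset` from the TSS, inside the scanned
#' window. Per-promoter cohort YC fractions, tag weights, trajectory and
#' motif labels are drawn here and recorded in the registry.
#'
#' @param config A [synthetic_config()] object.
#' @return A list: `genome` (a `genome_store`), `genes` (gene models as
#'   from [read_gtf_genes()]), `promoters` (registry data.frame),
#'   `ctss_registry` (per designed CTSS: promoter, position, class,
#'   subtype, within-promoter weight), `yc_fraction` (promoters x cohorts
#'   matrix of true fractions), `config`.
#' @export
generate_genome_and_annotation <- function(config) {
  set.seed(config$seed)
  margin <- 300L
  core_span <- 18L
  if (config$spacing < core_span + abs(config$motif_offset) + 50L)
    stopf("promoter spacing %d too small; need at least %d bp",
          config$spacing, core_span + abs(config$motif_offset) + 50L)
  per_contig <- ceiling(config$n_promoters / config$n_contigs)
  contig_len <- margin * 2L + per_contig * config$spacing
  contigs <- sprintf("chrS%d", seq_len(config$n_contigs))
  vecs <- lapply(contigs, function(ct)
    sample(c("A", "C", "G", "T"), contig_len, replace = TRUE))
  names(vecs) <- contigs

  n <- config$n_promoters
  k <- length(config$cohorts)
  prom <- data.frame(
    promoter = seq_len(n),
    gene_id = sprintf("G%04d", seq_len(n)),
    contig = contigs[((seq_len(n) - 1L) %% config$n_contigs) + 1L],
    slot = ((seq_len(n) - 1L) %/% config$n_contigs),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  prom$core <- margin + prom$slot * config$spacing
  prom$dual <- seq_len(n) <= round(config$dip_fraction * n)
  n_dual <- sum(prom$dual)
  prom$trajectory <- prom$dual &
    seq_len(n) <= round(config$trajectory_fraction * n_dual)
  prom$signature <- prom$trajectory
  plant_rate <- ifelse(prom$signature, config$motif_rate[["signature"]],
                       config$motif_rate[["background"]])
  prom$motif <- stats::runif(n) < plant_rate

  # truncated-Pareto tag weight per promoter
  u <- stats::runif(n)
  a <- config$tag_exponent
  cap_u <- 1 - config$weight_cap^(-a)
  prom$weight <- (1 - u * cap_u)^(-1 / a)

  # per-cohort true YC fractions
  conc <- config$yc_concentration
  f <- matrix(0, nrow = n, ncol = k,
              dimnames = list(prom$gene_id, config$cohorts))
  mid <- config$cohorts[ceiling(k / 2)]
  offsets <- config$trajectory_delta * seq(1, -1, length.out = k)
  for (i in seq_len(n)) {
    if (!prom$dual[i]) next
    if (prom$trajectory[i]) {
      m <- config$yc_mean[[mid]]
      base <- stats::rbeta(1, m * conc, (1 - m) * conc)
      f[i, ] <- stats::plogis(stats::qlogis(base) + offsets)
    } else {
      for (j in seq_len(k)) {
        m <- config$yc_mean[[config$cohorts[j]]]
        f[i, j] <- stats::rbeta(1, m * conc, (1 - m) * conc)
      }
    }
  }

  # designed CTSS: transcript-ordered offsets 0, 6, 12, 18 from the TSS
  offs <- c(0L, 6L, 12L, 18L)
  within_w <- c(0.7, 0.3)
  ctss_rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- prom$strand[i]
    tss <- if (st == "+") prom$core[i] else prom$core[i] + core_span
    gpos <- if (st == "+") tss + offs else tss - offs
    classes <- if (prom$dual[i]) c("YC", "YC", "YR", "YR")
      else c("YR", "YR", "YR", "YR")
    subtypes <- rep(NA_character_, 4)
    vec <- vecs[[prom$contig[i]]]
    for (j in 1:4) {
      if (classes[j] == "YC") {
        subtypes[j] <- sample(names(config$top_fraction), 1,
                              prob = config$top_fraction)
        pent <- draw_yc_pentamer(subtypes[j])
        vec <- write_context(vec, gpos[j], st, sample(PYRIMIDINES, 1), pent)
      } else {
        di <- sample(YR_DINUCS, 1)
        vec <- write_context(vec, gpos[j], st,
                             substr(di, 1, 1), substr(di, 2, 2))
      }
    }
    if (prom$motif[i]) {
      m <- config$motif_consensus
      w <- nchar(m)
      if (st == "+") {
        from <- tss + config$motif_offset          # 0-based start
        vec[from + seq_len(w)] <- strsplit(m, "")[[1]]
      } else {
        to <- tss - config$motif_offset            # 0-based end of motif
        vec[to + 2L - seq_len(w)] <- COMP[strsplit(m, "")[[1]]]
      }
    }
    vecs[[prom$contig[i]]] <- vec
    # within-class weights: first CTSS of each class carries 0.7, second 0.3
    ctss_rows[[i]] <- data.frame(promoter = i, gene_id = prom$gene_id[i],
                                 contig = prom$contig[i], strand = st,
                                 pos = gpos, class = classes,
                                 subtype = subtypes,
                                 within_weight = rep(within_w, 2),
                                 stringsAsFactors = FALSE)
  }
  ctss_registry <- do.call(rbind, ctss_rows)

  prom$tss <- ifelse(prom$strand == "+", prom$core, prom$core + core_span)
  genes <- data.frame(gene_id = prom$gene_id, contig = prom$contig,
                      strand = prom$strand, tss = prom$tss,
                      start = ifelse(prom$strand == "+", prom$tss,
                                     prom$tss - 399L),
                      end = ifelse(prom$strand == "+", prom$tss + 400L,
                                   prom$tss + 1L),
                      stringsAsFactors = FALSE)
  genome <- genome_store(vapply(vecs, paste, "", collapse = ""))
  list(genome = genome, genes = genes, promoters = prom,
       ctss_registry = ctss_registry, yc_fraction = f, config = config)
}

#' Write the synthetic annotation as GTF
#'
#' @param genes Gene models (0-based) from the generator.
#' @param path Output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- sprintf(
    '%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    genes$contig, genes$start + 1L, genes$end, genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

# YC fraction after multiplying YC mass by m (YR mass unchanged).
apply_treatment <- function(f, m) f * m / (f * m + (1 - f))

#' Generate per-sample CTSS tag tables and the ground truth
#'
#' Per sample, `depth` tags are distributed over the designed CTSS by a
#' multinomial whose weights combine the promoter's truncated-Pareto tag
#' weight, the cohort-specific YC fraction (multiplied by the treatment
#' effect in irradiated libraries), and within-promoter CTSS weights;
#' intergenic noise tags at `noise_rate` per kb land at uniform positions
#' (outside promoter cores) with whatever initiator context the random
#' genome provides.
#'
#' @param config A [synthetic_config()] object.
#' @param gen Output of [generate_genome_and_annotation()].
#' @return A list: `ctss` (merged multi-sample CTSS table), `tables`
#'   (per-sample single-sample tables), `sample_sheet`, `truth` (list with
#'   `promoters` incl. expected per-sample class TPM and DIP status,
#'   `yc_fraction`, per-sample true fraction matrix `f_sample`,
#'   `ctss_registry`).
#' @export
generate_ctss_samples <- function(config, gen) {
  set.seed(config$seed + 1L)
  reg <- gen$ctss_registry
  prom <- gen$promoters
  f <- gen$yc_fraction

  sheet <- expand.grid(rep = seq_len(config$samples_per_cohort),
                       cohort = config$cohorts, stringsAsFactors = FALSE)
  sheet$base <- sprintf("%s_%d", sheet$cohort, sheet$rep)
  if (config$treatment) {
    sheet <- sheet[rep(seq_len(nrow(sheet)), each = 2L), ]
    sheet$treatment <- rep(c("control", "irradiated"), length.out = nrow(sheet))
    sheet$sample <- paste0(sheet$base, "_", substr(sheet$treatment, 1, 4))
    sheet$pair <- sheet$base
  } else {
    sheet$treatment <- "control"
    sheet$sample <- sheet$base
    sheet$pair <- ""
  }
  sheet <- data.frame(sample = sheet$sample, path = "", cohort = sheet$cohort,
                      pair = sheet$pair, treatment = sheet$treatment,
                      stringsAsFactors = FALSE)

  total_kb <- sum(as.numeric(gen$genome$lengths)) / 1000
  core_lo <- prom$core - 30L
  core_hi <- prom$core + 48L

  n_s <- nrow(sheet)
  f_sample <- matrix(0, nrow = nrow(prom), ncol = n_s,
                     dimnames = list(prom$gene_id, sheet$sample))
  tables <- vector("list", n_s)
  names(tables) <- sheet$sample
  exp_tpm <- array(0, dim = c(nrow(prom), n_s, 2),
                   dimnames = list(prom$gene_id, sheet$sample, c("YC", "YR")))
  for (s in seq_len(n_s)) {
    co <- sheet$cohort[s]
    fs <- f[, co]
    if (sheet$treatment[s] == "irradiated")
      fs <- apply_treatment(fs, config$treatment_effect[[co]])
    f_sample[, s] <- fs
    class_share <- ifelse(reg$class == "YC", fs[reg$promoter],
                          1 - fs[reg$promoter])
    wts <- prom$weight[reg$promoter] * class_share * reg$within_weight
    counts <- as.integer(stats::rmultinom(1, config$depth, wts))
    keep <- counts > 0
    tab <- data.frame(contig = reg$contig[keep], pos = reg$pos[keep],
                      strand = reg$strand[keep], stringsAsFactors = FALSE)
    tab[[paste0("count.", sheet$sample[s])]] <- counts[keep]

    n_noise <- stats::rpois(1, config$noise_rate * total_kb)
    if (n_noise > 0) {
      nc <- sample(names(gen$genome$lengths), n_noise, replace = TRUE)
      npos <- floor(stats::runif(n_noise) * (gen$genome$lengths[nc] - 1))
      in_core <- vapply(seq_len(n_noise), function(i) {
        pi <- which(prom$contig == nc[i])
        any(npos[i] >= core_lo[pi] & npos[i] <= core_hi[pi])
      }, TRUE)
      nc <- nc[!in_core]; npos <- npos[!in_core]
      if (length(npos)) {
        ntab <- data.frame(contig = nc, pos = as.integer(npos),
                           strand = sample(c("+", "-"), length(npos),
                                           replace = TRUE),
                           stringsAsFactors = FALSE)
        ntab$count <- 1L + stats::rpois(length(npos), 0.3)
        key <- paste(ntab$contig, ntab$pos, ntab$strand)
        ntab <- ntab[!duplicated(key), , drop = FALSE]
        names(ntab)[4] <- paste0("count.", sheet$sample[s])
        tab <- merge_ctss(list(tab, ntab))
      }
    }
    tables[[s]] <- order_ctss(tab)
    share <- prom$weight / sum(prom$weight)
    exp_tpm[, s, "YC"] <- 1e6 * share * fs
    exp_tpm[, s, "YR"] <- 1e6 * share * (1 - fs)
  }

  merged <- merge_ctss(tables)
  truth_prom <- prom
  qual <- exp_tpm[, , "YC"] > 1 & exp_tpm[, , "YR"] > 1
  truth_prom$dip <- rowSums(qual) > 0.5 * n_s
  truth_prom$true_monotone <- apply(f, 1, function(v)
    all(diff(v) < 0)) & prom$dual
  list(ctss = merged, tables = tables, sample_sheet = sheet,
       truth = list(promoters = truth_prom, yc_fraction = f,
                    f_sample = f_sample, expected_tpm = exp_tpm,
                    ctss_registry = reg))
}

#' Compare pipeline output with synthetic truth
#'
#' @param run A `dip_run` object from [run_pipeline()].
#' @param truth The `truth` element from [generate_ctss_samples()].
#' @param trajectory Optional [trajectory_select()] result on the run's
#'   DIP ratios (gene-level names).
#' @return A list of recovery metrics: `dip_sensitivity`, `dip_fdr`,
#'   `spearman_yc_fraction`, and (when `trajectory` is given)
#'   `trajectory_recall` (vs planted trajectories) and
#'   `trajectory_precision` (vs all promoters whose true cohort fractions
#'   are strictly ordered).
#' @export
truth_compare <- function(run, truth, trajectory = NULL) {
  tp <- truth$promoters
  true_dips <- tp$gene_id[tp$dip]
  called <- names(run$dips)[run$dips]
  if (length(intersect(rownames(run$gene$tpm), tp$gene_id)) == 0L)
    stopf("gene ids of the run and the truth do not match")
  sens <- if (length(true_dips)) length(intersect(called, true_dips)) /
    length(true_dips) else NA_real_
  fdr <- if (length(called)) length(setdiff(called, true_dips)) /
    length(called) else 0

  yc <- run$gene$class_tpm$YC
  yr <- run$gene$class_tpm$YR
  est_frac <- rowSums(yc) / pmax(rowSums(yc) + rowSums(yr), 1e-12)
  dual_genes <- intersect(tp$gene_id[tp$dual], rownames(yc))
  true_frac <- rowMeans(truth$f_sample)[dual_genes]
  sp <- stats::cor(est_frac[dual_genes], true_frac, method = "spearman")

  out <- list(dip_sensitivity = sens, dip_fdr = fdr,
              spearman_yc_fraction = sp,
              n_true_dips = length(true_dips), n_called_dips = length(called))
  if (!is.null(trajectory)) {
    planted <- tp$gene_id[tp$trajectory]
    sel <- trajectory$selected
    out$trajectory_recall <- if (length(planted))
      length(intersect(sel, planted)) / length(planted) else NA_real_
    truly_mono <- tp$gene_id[tp$true_monotone]
    out$trajectory_precision <- if (length(sel))
      length(intersect(sel, truly_mono)) / length(sel) else NA_real_
  }
  out
}
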