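# Independent oracles: brute-force or table-lookup implementations kept
# deliberately separate from the package's code paths.

# O(n^2) transitive closure: build the full pairwise linkage graph and
# take its connected components (igraph), independent of the package's
# sorted single-pass implementation.
oracle_components <- function(adj, first_by) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  match(comp, unique(comp[order(first_by)]))
}

oracle_cluster_positions <- function(pos, max_gap) {
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  oracle_components(adj, pos)
}

# Spans linked when the inter-span gap is <= dist.
oracle_cluster_spans <- function(start, end, dist) {
  gap <- outer(start, end, function(s, e) s - e)
  adj <- pmax(gap, t(gap)) <= dist
  oracle_components(adj, start)
}

# Literal lookup of the initiator dinucleotide classes.
oracle_dinuc_table <- local({
  all16 <- expand.grid(m = c("A", "C", "G", "T"), p = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  di <- paste0(all16$m, all16$p)
  cls <- rep("OTHER", 16)
  cls[di %in% c("CA", "CG", "TA", "TG")] <- "YR"
  cls[di %in% c("CC", "TC")] <- "YC"
  stats::setNames(cls, di)
})

# Pyrimidine-count 5-mer subtype by character arithmetic.
oracle_pentamer_class <- function(p5) {
  b <- strsplit(p5, "")[[1]]
  npyr <- sum(b == "C") + sum(b == "T")
  if (b[1] != "C") return(NA_character_)
  if (npyr == 5) "TOP" else if (npyr == 4) "TOP_DEG" else "YC_OTHER"
}

# Direct formula for one PWM cell.
oracle_pwm_weight <- function(count, colsum, pseudocount, bg_b) {
  log2((count + pseudocount * bg_b) / (colsum + pseudocount) / bg_b)
}

# Two-sided Fisher p by full enumeration of tables with fixed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(x) stats::dhyper(x, c1, n - c1, r1), 0)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Independently coded power-law normalization (lm on reverse cumulative,
# closed-form reference intercept via the same total-matching definition).
oracle_powerlaw <- function(counts, alpha_ref = 1.05, t_ref = 1e6,
                            fit_range = c(5, 1000)) {
  v <- sort(unique(counts[counts > 0]))
  v <- v[v >= fit_range[1] & v <= fit_range[2]]
  num <- sapply(v, function(x) sum(counts >= x))
  co <- stats::coef(stats::lm(log10(num) ~ log10(v)))
  a <- -co[[2]]; x0s <- 10^(co[[1]] / a)
  tot <- function(x0) alpha_ref / (alpha_ref - 1) * x0^alpha_ref *
    (1 - x0^(1 - alpha_ref)) - t_ref
  x0r <- stats::uniroot(tot, c(1 + 1e-9, 1e15), tol = 1e-9)$root
  ifelse(counts > 0, (counts / x0s)^(a / alpha_ref) * x0r, 0)
}

# Per-row DIP rule check.
oracle_call_dips <- function(yc, yr, thr, frac) {
  out <- logical(nrow(yc))
  for (i in seq_len(nrow(yc))) {
    q <- 0
    for (s in seq_len(ncol(yc))) if (yc[i, s] > thr && yr[i, s] > thr) q <- q + 1
    out[i] <- q > frac * ncol(yc)
  }
  out
}
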