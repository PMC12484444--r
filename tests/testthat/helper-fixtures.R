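# Small, fast configurations and hand-built fixtures shared across tests.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_individuals = 300, n_variants = 120, n_genes = 30,
             cells_per_type = 30, discovery_n = 1500, seed = seed, ...)
}

# toy variant table aligned to a dosage matrix built column by column
toy_variants <- function(chrom, pos, pvalue,
                         beta = rep(0.1, length(pos))) {
  data.frame(chrom = chrom, pos = pos,
             id = sprintf("v%02d", seq_along(pos)),
             ea = "A", oa = "G", beta = beta, pvalue = pvalue,
             col_index = seq_along(pos), stringsAsFactors = FALSE)
}

# brute-force clumping reference: repeatedly take the globally most
# significant unassigned variant, then scan all other unassigned
# variants with explicit loops and the textbook correlation formula
naive_clump <- function(variants, dosage, r2 = 0.1, window_kb = 1000) {
  m <- nrow(variants)
  status <- rep("open", m)
  window <- window_kb * 1000
  r2_pair <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
    if (sx == 0 || sy == 0) return(0)
    (sum((x - mean(x)) * (y - mean(y)))^2) / (sx * sy)
  }
  repeat {
    open <- which(status == "open")
    if (!length(open)) break
    o <- open[order(variants$pvalue[open], variants$chrom[open],
                    variants$pos[open])][1]
    status[o] <- "index"
    for (j in which(status == "open")) {
      if (variants$chrom[j] != variants$chrom[o]) next
      if (abs(variants$pos[j] - variants$pos[o]) > window) next
      if (r2_pair(dosage[, variants$col_index[j]],
                  dosage[, variants$col_index[o]]) > r2)
        status[j] <- "clumped"
    }
  }
  status == "index"
}

# brute-force nearest gene: full scan with explicit tie-breaking
naive_nearest <- function(chrom, pos, ann) {
  best <- NULL
  for (g in seq_len(nrow(ann))) {
    if (ann$chrom[g] != chrom) next
    d <- if (pos >= ann$start[g] && pos <= ann$end[g]) 0
         else min(abs(pos - ann$start[g]), abs(pos - ann$end[g]))
    rec <- list(gene = ann$gene_id[g], d = d, start = ann$start[g])
    if (is.null(best) || d < best$d ||
        (d == best$d && rec$start < best$start) ||
        (d == best$d && rec$start == best$start && rec$gene < best$gene))
      best <- rec
  }
  best
}

# step-up BH reference, written independently of stats::p.adjust
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
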