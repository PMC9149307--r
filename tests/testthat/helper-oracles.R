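# Independent brute-force oracles. These deliberately re-derive each
# quantity with plain loops so they share no code with the implementation.

# Guide z-scores: explicit per-guide window enumeration for one
# treatment/control pairing (equal numbers of samples assumed paired i-i).
brute_guide_z <- function(counts, treatment, control, pseudocount = 5,
                          half_window = 500, sd_floor = 1e-3) {
  out <- list()
  for (k in seq_along(treatment)) {
    trt <- counts[[treatment[k]]]
    ctl <- counts[[control[k]]]
    fc <- log2((trt + pseudocount) / (ctl + pseudocount))
    ord <- order(ctl, decreasing = TRUE)
    n <- length(fc)
    z <- numeric(n)
    for (pos in seq_len(n)) {
      if (n < 2 * half_window + 1) {
        win <- seq_len(n)
      } else {
        win <- max(1, pos - half_window):min(n, pos + half_window)
      }
      s <- max(sd(fc[ord][win]), sd_floor)
      z[ord[pos]] <- fc[ord[pos]] / s
    }
    out[[k]] <- data.frame(guide_id = counts$guide_id,
                           gene_id = counts$gene_id,
                           pairing = k, fold_change = fc, z = z)
  }
  do.call(rbind, out)
}

# Benjamini-Hochberg by its textbook definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# AUROC by exhaustive pairwise comparison, ties worth one half.
brute_auroc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(pos) * length(neg))
}

# Gene-level aggregation by per-gene scan.
brute_aggregate <- function(scored, gene_col, partner_col) {
  genes <- unique(scored[[gene_col]])
  rows <- lapply(genes, function(g) {
    sub <- scored[scored[[gene_col]] == g, ]
    best <- sub[abs(sub$z_final) == max(abs(sub$z_final)), ]
    best <- best[order(best[[partner_col]]), ][1, ]
    data.frame(gene_id = g, partner = best[[partner_col]],
               z_final = best$z_final)
  })
  do.call(rbind, rows)
}

# Shortlist filter applied rule by rule to each row.
brute_shortlist <- function(scored, expressed_ctl_genes,
                            fdr_threshold = 0.05, abs_z_threshold = 3) {
  z_cols <- grep("^z_tnbc_", names(scored), value = TRUE)
  keep <- logical(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    row <- scored[i, ]
    pass1 <- row$fdr < fdr_threshold || abs(row$z_final) > abs_z_threshold
    signs <- sign(c(row$z_ctl, unlist(row[z_cols]), row$z_final))
    signs <- signs[signs != 0]
    pass2 <- length(signs) == 0 || all(signs == signs[1])
    pass3 <- row$ctl_gene %in% expressed_ctl_genes
    keep[i] <- pass1 && pass2 && pass3
  }
  scored[keep, ]
}

# Small shared fixtures -------------------------------------------------

tiny_counts <- function(n_guides = 50, n_genes = 10, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    guide_id = paste0("g", seq_len(n_guides)),
    gene_id = paste0("gene", rep_len(seq_len(n_genes), n_guides)),
    trt1 = as.numeric(rnbinom(n_guides, mu = 300, size = 10)),
    trt2 = as.numeric(rnbinom(n_guides, mu = 300, size = 10)),
    ctl1 = as.numeric(rnbinom(n_guides, mu = 300, size = 10)),
    ctl2 = as.numeric(rnbinom(n_guides, mu = 300, size = 10))
  )
}

make_calls <- function(context, genes, expressed = TRUE) {
  tibble::tibble(context = context, gene_id = genes,
                 mean_expression = NA_real_,
                 expressed = rep_len(expressed, length(genes)))
}

make_tnbc_scores <- function(lines, genes, z_by_line) {
  purrr::map_dfr(seq_along(lines), function(i) {
    tibble::tibble(cell_line = lines[i], gene_id = genes,
                   normZ = z_by_line[[i]])
  })
}
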