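#' Enumerate oriented ligand-receptor instances between the two cell types
#'
#' Each catalog pair can be realized in two ways across an immune/cancer
#' cell boundary: the ligand on the CTL and the receptor on the cancer
#' cell, or the reverse. Both orientations are scored as separate
#' instances; a self-pair whose two orientations coincide (identical ligand
#' and receptor gene) is emitted once.
#'
#' @param catalog An interaction catalog ([read_catalog()]), columns
#'   `ligand_gene`, `receptor_gene`.
#'
#' @return A tibble `ctl_gene`, `tnbc_gene`, `ctl_role` (`"ligand"` or
#'   `"receptor"`), `ligand_gene`, `receptor_gene`.
#' @export
enumerate_oriented <- function(catalog) {
  lig_on_ctl <- catalog |>
    dplyr::transmute(ctl_gene = .data$ligand_gene,
                     tnbc_gene = .data$receptor_gene,
                     ctl_role = "ligand",
                     ligand_gene = .data$ligand_gene,
                     receptor_gene = .data$receptor_gene)
  lig_on_tnbc <- catalog |>
    dplyr::filter(.data$ligand_gene != .data$receptor_gene) |>
    dplyr::transmute(ctl_gene = .data$receptor_gene,
                     tnbc_gene = .data$ligand_gene,
                     ctl_role = "receptor",
                     ligand_gene = .data$ligand_gene,
                     receptor_gene = .data$receptor_gene)
  dplyr::bind_rows(lig_on_ctl, lig_on_tnbc)
}

#' Stouffer combination of two normZ scores with an optional sign constraint
#'
#' The Tolerant rule always returns `(z1 + z2) / sqrt(2)`, which is standard
#' normal when both inputs are. The Strict rule returns the same quantity
#' only when the two scores do not actively disagree in sign -- a zero score
#' (typically an expression-gated gene) is compatible with anything -- and
#' zero otherwise.
#'
#' @param z1,z2 Numeric vectors of normZ scores (recycled).
#' @param mode `"tolerant"` or `"strict"`.
#' @return The combined score(s).
#' @export
#'
#' @examples
#' combine_two(1.5, -2.0, "tolerant") # (1.5 - 2.0) / sqrt(2)
#' combine_two(1.5, -2.0, "strict")   # 0
combine_two <- function(z1, z2, mode = c("tolerant", "strict")) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(z1)), all(is.finite(z2)))
  out <- (z1 + z2) / sqrt(2)
  if (mode == "strict") {
    out[z1 * z2 < 0] <- 0
  }
  out
}

# Across-cell-line combination: sum / sqrt(n); under "strict" the result
# is zeroed when the cell lines disagree -- any two nonzero cancer-side
# gene scores (or, equivalently when the CTL score is zero, pair scores)
# with opposite signs.
combine_lines <- function(zs, mode = c("tolerant", "strict"),
                          inputs = zs) {
  mode <- match.arg(mode)
  if (mode == "strict") {
    nz <- c(zs[zs != 0], inputs[inputs != 0])
    if (any(nz > 0) && any(nz < 0)) {
      return(0)
    }
  }
  sum(zs) / sqrt(length(zs))
}

#' Score every oriented ligand-receptor instance
#'
#' For each oriented instance the gated CTL-side score and the gated
#' cancer-side score in each cell line are combined in two Stouffer stages:
#' within the ligand-receptor pair (giving one cell-line-specific
#' intercellular normZ per cancer cell line) and then across cell lines
#' (dividing the sum by the square root of the number of lines). The three
#' methods differ only in where a sign constraint applies:
#'
#' * `tolerant` -- no constraint at either stage;
#' * `strict` -- opposite nonzero signs zero the result within the pair,
#'   and discordant nonzero cancer-side scores across cell lines zero the
#'   final score;
#' * `composite` -- sign agreement required within the ligand-receptor pair
#'   but not across cancer cell lines (cell lines are heterogeneous and may
#'   genuinely disagree).
#'
#' Genes absent from a score table contribute 0 (their count is reported
#' via `message()`), consistent with expression gating.
#'
#' @param oriented Oriented instances from [enumerate_oriented()].
#' @param ctl_scores Gated gene normZ table for the CTL context
#'   (`gene_id`, `normZ`).
#' @param tnbc_scores Gated cancer-side scores in long form:
#'   `cell_line`, `gene_id`, `normZ`.
#' @param method `"tolerant"`, `"strict"` or `"composite"`.
#'
#' @return A tibble with one row per oriented instance: the identifier
#'   columns of `oriented`, `z_ctl`, one `z_tnbc_<line>` and one
#'   `z_pair_<line>` column per cell line, `z_final`, `method`.
#' @export
score_interactions <- function(oriented, ctl_scores, tnbc_scores,
                               method = c("tolerant", "strict", "composite")) {
  method <- match.arg(method)
  stopifnot(all(c("cell_line", "gene_id", "normZ") %in% names(tnbc_scores)))
  pair_mode <- if (method == "tolerant") "tolerant" else "strict"
  line_mode <- if (method == "strict") "strict" else "tolerant"

  lines <- sort(unique(tnbc_scores$cell_line))
  ctl_lookup <- setNames(ctl_scores$normZ, ctl_scores$gene_id)
  line_lookups <- purrr::map(lines, function(l) {
    tab <- tnbc_scores[tnbc_scores$cell_line == l, ]
    setNames(tab$normZ, tab$gene_id)
  })
  names(line_lookups) <- lines

  lookup0 <- function(map, genes) {
    z <- unname(map[genes])
    z[is.na(z)] <- 0
    z
  }

  n_absent_ctl <- sum(!unique(oriented$ctl_gene) %in% names(ctl_lookup))
  n_absent_tnbc <- sum(!unique(oriented$tnbc_gene) %in% tnbc_scores$gene_id)
  message("score_interactions: ", nrow(oriented), " oriented instances; ",
          n_absent_ctl, " CTL-side and ", n_absent_tnbc,
          " cancer-side genes absent from the screens (scored 0)")

  out <- oriented
  out$z_ctl <- lookup0(ctl_lookup, oriented$ctl_gene)
  pair_mat <- matrix(0, nrow(out), length(lines))
  input_mat <- matrix(0, nrow(out), length(lines))
  for (i in seq_along(lines)) {
    z_t <- lookup0(line_lookups[[i]], oriented$tnbc_gene)
    out[[paste0("z_tnbc_", lines[i])]] <- z_t
    input_mat[, i] <- z_t
    pair_mat[, i] <- combine_two(out$z_ctl, z_t, pair_mode)
    out[[paste0("z_pair_", lines[i])]] <- pair_mat[, i]
  }
  out$z_final <- vapply(seq_len(nrow(out)), function(r) {
    combine_lines(pair_mat[r, ], mode = line_mode, inputs = input_mat[r, ])
  }, numeric(1))
  out$method <- method
  out
}

#' Attach one-sided p-values and per-direction BH false discovery rates
#'
#' Because a final intercellular normZ is standard normal under the null,
#' its one-sided p-value is the normal tail beyond it in its own direction
#' (`p = pnorm(-|z|)`; a score of exactly 0 has p = 0.5). CTL-activating
#' (positive) and CTL-suppressive (negative) calls are separate discovery
#' problems, so Benjamini-Hochberg correction is applied within the
#' positive-score instances and within the negative-score instances
#' independently, and each instance reports the FDR of its own direction.
#'
#' @param scored Output of [score_interactions()].
#' @return `scored` with columns `p` and `fdr` appended.
#' @export
scores_to_significance <- function(scored) {
  if (nrow(scored) == 0) {
    stop("scores_to_significance: empty score table", call. = FALSE)
  }
  stopifnot("z_final" %in% names(scored))
  scored$p <- pnorm(-abs(scored$z_final))
  pos <- scored$z_final >= 0
  scored$fdr <- NA_real_
  scored$fdr[pos] <- p.adjust(scored$p[pos], method = "BH")
  scored$fdr[!pos] <- p.adjust(scored$p[!pos], method = "BH")
  scored
}

#' Aggregate interaction scores to gene-level scores
#'
#' A gene takes part in many ligand-receptor instances; for comparison with
#' single-screen gene rankings, its gene-level score is the intercellular
#' normZ of its instance with the largest absolute value. Ties are broken
#' by the lexicographically smallest partner gene.
#'
#' @param scored A significance-annotated score table.
#' @param side `"ctl"` (aggregate over `ctl_gene`) or `"tnbc"`.
#' @return A tibble `side`, `gene_id`, `partner`, `z_final`, `p`, `fdr`.
#' @export
gene_level_aggregate <- function(scored, side = c("ctl", "tnbc")) {
  side <- match.arg(side)
  if (nrow(scored) == 0) {
    stop("gene_level_aggregate: empty score table", call. = FALSE)
  }
  gene_col <- if (side == "ctl") "ctl_gene" else "tnbc_gene"
  partner_col <- if (side == "ctl") "tnbc_gene" else "ctl_gene"
  agg <- scored |>
    dplyr::mutate(gene_id = .data[[gene_col]],
                  partner = .data[[partner_col]]) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(abs(.data$z_final)),
                   .data$partner) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  tibble::tibble(
    side = side,
    gene_id = agg$gene_id,
    partner = agg$partner,
    z_final = agg$z_final,
    p = if ("p" %in% names(agg)) agg$p else NA_real_,
    fdr = if ("fdr" %in% names(agg)) agg$fdr else NA_real_
  )
}

#' Shortlist candidate interactions for follow-up
#'
#' Reproduces the candidate-selection rule applied to the ranked score
#' table: keep instances that are either significant (`fdr <
#' fdr_threshold`) or large (`|z_final| > abs_z_threshold`); then require
#' the screens to agree -- every nonzero gated score among the CTL side,
#' each cancer cell line and the final score must carry the same sign
#' (gated zeros are compatible with anything); finally require the CTL-side
#' gene to be expressed in CTLs. Cancer-side expression is deliberately not
#' required, so that genes expressed in only a subset of tumors (the
#' Cd274 situation) remain discoverable through the CTL side.
#'
#' @param scored Significance-annotated score table.
#' @param ctl_calls Expression calls containing the CTL context.
#' @param ctl_context Name of the CTL context in `ctl_calls`.
#' @param fdr_threshold FDR cutoff (strict `<`); default 0.05.
#' @param abs_z_threshold Absolute-score cutoff (strict `>`); default 3.
#' @return The retained rows of `scored`, ranked by decreasing `|z_final|`.
#' @export
shortlist_candidates <- function(scored, ctl_calls, ctl_context = "CTL",
                                 fdr_threshold = 0.05, abs_z_threshold = 3) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  z_cols <- grep("^z_tnbc_", names(scored), value = TRUE)
  expressed_ctl <- ctl_calls$gene_id[ctl_calls$context == ctl_context &
                                       ctl_calls$expressed]
  keep_mag <- scored$fdr < fdr_threshold | abs(scored$z_final) > abs_z_threshold
  sign_mat <- cbind(sign(scored$z_ctl),
                    do.call(cbind, lapply(z_cols, function(cl) {
                      sign(scored[[cl]])
                    })),
                    sign(scored$z_final))
  concordant <- apply(sign_mat, 1, function(s) {
    nz <- s[s != 0]
    length(nz) == 0 || all(nz == nz[1])
  })
  keep <- keep_mag & concordant & scored$ctl_gene %in% expressed_ctl
  message("shortlist_candidates: ", sum(keep), " of ", nrow(scored),
          " instances retained")
  scored[keep, ] |>
    dplyr::arrange(dplyr::desc(abs(.data$z_final)))
}
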