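#' Call expressed genes from a bulk-expression table
#'
#' A gene is called expressed in a cell context when its mean FPKM across
#' replicates is at least `threshold` (inclusive: "at least ten fragments
#' per kilobase" means a mean of exactly 10 passes). Genes measured by
#' several probes are collapsed to the probe with the highest mean before
#' thresholding.
#'
#' @param expression A tibble `gene_id`, `probe`, one numeric FPKM column
#'   per replicate (see [read_expression_table()]).
#' @param context Cell-context label (e.g. `"4T1"`, `"EMT6"`, `"CTL"`).
#' @param threshold FPKM cutoff; default 10.
#'
#' @return A tibble `context`, `gene_id`, `mean_expression`, `expressed`,
#'   one row per gene.
#' @export
call_expressed <- function(expression, context, threshold = 10) {
  stopifnot(threshold >= 0)
  rep_cols <- setdiff(names(expression), c("gene_id", "probe"))
  if (length(rep_cols) < 1) {
    stop("call_expressed: no replicate columns", call. = FALSE)
  }
  expression |>
    dplyr::mutate(.mean = rowMeans(dplyr::pick(dplyr::all_of(rep_cols)))) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice_max(.data$.mean, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      context = context,
      gene_id = .data$gene_id,
      mean_expression = .data$.mean,
      expressed = .data$.mean >= threshold
    )
}

#' Zero the normZ scores of genes not expressed in a cell context
#'
#' Knockout phenotypes of genes a cell does not express are treated as
#' screening noise: before ligand-receptor combination the normZ of every
#' gene not called expressed in the given context is set to zero. Genes
#' missing from the call set entirely are conservatively treated as
#' unexpressed and zeroed too (their count is reported via `message()`).
#' The operation is idempotent and can only shrink scores.
#'
#' @param gene_scores A gene normZ table ([gene_normz()]).
#' @param calls Expression calls ([call_expressed()], [read_gene_list()]).
#' @param context Which context's calls to apply.
#'
#' @return The table with gated `normZ` and a logical `expressed` column.
#' @export
gate_scores <- function(gene_scores, calls, context) {
  ctx <- dplyr::filter(calls, .data$context == !!context)
  if (nrow(ctx) == 0 && nrow(calls) > 0) {
    stop("gate_scores: context '", context, "' not present in calls",
         call. = FALSE)
  }
  expressed_genes <- ctx$gene_id[ctx$expressed]
  out <- gene_scores |>
    dplyr::mutate(
      expressed = .data$gene_id %in% expressed_genes,
      normZ = dplyr::if_else(.data$expressed, .data$normZ, 0)
    )
  n_absent <- sum(!out$gene_id %in% ctx$gene_id)
  n_zeroed <- sum(!out$expressed)
  message("gate_scores[", context, "]: zeroed ", n_zeroed, " of ",
          nrow(out), " genes (", n_absent, " absent from the call set)")
  out
}
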