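#' Read a guide-count matrix
#'
#' Expects a tab-separated file with a header row; the first two columns are
#' the guide identifier and the gene identifier, every remaining column is a
#' numeric count for one sample. Gene symbols are kept as-is (case-sensitive;
#' mouse-style capitalization such as `Cd274` is never upper-cased).
#'
#' @param path Path to the TSV file.
#' @param treatment,control Optional character vectors naming the sample
#'   columns playing each role; when given, every name must be present.
#'
#' @return A tibble `guide_id`, `gene_id`, one numeric column per sample,
#'   with attribute `sample_roles` (named character vector) when roles were
#'   supplied.
#' @export
read_guide_counts <- function(path, treatment = NULL, control = NULL) {
  counts <- readr::read_tsv(path, show_col_types = FALSE,
                            progress = FALSE)
  if (ncol(counts) < 3) {
    stop("read_guide_counts: expected guide id, gene id and >=1 sample column",
         call. = FALSE)
  }
  names(counts)[1:2] <- c("guide_id", "gene_id")
  counts$guide_id <- as.character(counts$guide_id)
  counts$gene_id <- as.character(counts$gene_id)
  counts <- validate_guide_counts(counts)
  roles <- c(treatment, control)
  if (length(roles) > 0) {
    missing <- setdiff(roles, guide_sample_cols(counts))
    if (length(missing) > 0) {
      stop("read_guide_counts: sample(s) named in role map not in file: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    attr(counts, "sample_roles") <-
      setNames(c(rep("treatment", length(treatment)),
                 rep("control", length(control))), roles)
  }
  counts
}

validate_guide_counts <- function(counts) {
  stopifnot(all(c("guide_id", "gene_id") %in% names(counts)))
  sample_cols <- guide_sample_cols(counts)
  if (length(sample_cols) == 0) {
    stop("guide-count table has no sample columns", call. = FALSE)
  }
  not_num <- sample_cols[!vapply(counts[sample_cols], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("non-numeric count column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(counts[sample_cols], function(x) any(!is.finite(x) | x < 0),
                 logical(1)))) {
    stop("guide-count table contains negative or non-finite counts",
         call. = FALSE)
  }
  dup <- unique(counts$guide_id[duplicated(counts$guide_id)])
  if (length(dup) > 0) {
    stop("duplicate guide id(s): ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(counts)
}

guide_sample_cols <- function(counts) {
  setdiff(names(counts), c("guide_id", "gene_id"))
}

#' Read a ligand-receptor interaction catalog
#'
#' A TSV with columns for the ligand gene, the receptor gene and optionally
#' a source database. Ligand and receptor are distinct roles, so `(A, B)`
#' and `(B, A)` are different pairs; identical ordered pairs listed by
#' several sources are merged into one row with the sources joined by `;`.
#'
#' @param path Path to the TSV file.
#' @return A tibble `ligand_gene`, `receptor_gene`, `source` with unique
#'   ordered pairs, plus attribute `n_unordered` (distinct unordered pairs).
#' @export
read_catalog <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) {
    stop("read_catalog: catalog file is empty", call. = FALSE)
  }
  names(tab)[1:2] <- c("ligand_gene", "receptor_gene")
  if (!"source" %in% names(tab)) tab$source <- NA_character_
  cat <- tab |>
    dplyr::group_by(.data$ligand_gene, .data$receptor_gene) |>
    dplyr::summarise(
      source = paste(unique(stats::na.omit(.data$source)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(source = dplyr::if_else(.data$source == "",
                                          NA_character_, .data$source))
  key <- purrr::map2_chr(cat$ligand_gene, cat$receptor_gene,
                         ~ paste(sort(c(.x, .y)), collapse = "\r"))
  attr(cat, "n_unordered") <- dplyr::n_distinct(key)
  cat
}

#' Read an expression table or expressed-gene list
#'
#' `read_expression_table()` reads a bulk-expression TSV whose first two
#' columns are gene and probe, followed by one FPKM column per replicate.
#' `read_gene_list()` reads a plain text file with one gene symbol per line
#' and returns expression calls in which every listed gene is expressed
#' (used for contexts whose expressed-gene set comes from an external
#' single-cell analysis rather than bulk FPKM).
#'
#' @param path Path to the file.
#' @return For `read_expression_table()`, a tibble `gene_id`, `probe`,
#'   replicate columns. For `read_gene_list()`, an expression-call tibble
#'   (`context`, `gene_id`, `mean_expression`, `expressed`).
#' @export
read_expression_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 3) {
    stop("read_expression_table: expected gene, probe and >=1 replicate column",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("gene_id", "probe")
  rep_cols <- setdiff(names(tab), c("gene_id", "probe"))
  not_num <- rep_cols[!vapply(tab[rep_cols], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("read_expression_table: non-numeric FPKM column(s): ",
         paste(not_num, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' @param context Cell-context label recorded on each call.
#' @rdname read_expression_table
#' @export
read_gene_list <- function(path, context) {
  genes <- readr::read_lines(path, progress = FALSE)
  genes <- unique(genes[nzchar(trimws(genes))])
  tibble::tibble(
    context = context,
    gene_id = trimws(genes),
    mean_expression = NA_real_,
    expressed = TRUE
  )
}

#' Read a precomputed expression-call table
#'
#' TSV with columns `context`, `gene_id`, `mean_expression`, `expressed`
#' -- the long form written by the simulator and by [call_expressed()].
#'
#' @param path Path to the TSV file.
#' @return An expression-call tibble.
#' @export
read_expression_calls <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("context", "gene_id", "expressed") %in% names(tab)))
  if (!"mean_expression" %in% names(tab)) tab$mean_expression <- NA_real_
  tab$expressed <- as.logical(tab$expressed)
  tibble::as_tibble(tab)
}

#' Read a curated standard set
#'
#' TSV with columns `gene_a`, `gene_b`, `label` (`activating` or
#' `suppressive`) and optionally `tier` (`gold` or `silver`).
#'
#' @param path Path to the TSV file.
#' @return A tibble with those columns; pairs unique within tier.
#' @export
read_standards <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1:2] <- c("gene_a", "gene_b")
  if (!"label" %in% names(tab)) {
    stop("read_standards: missing 'label' column", call. = FALSE)
  }
  bad <- setdiff(unique(tab$label), c("activating", "suppressive"))
  if (length(bad) > 0) {
    stop("read_standards: unknown label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"tier" %in% names(tab)) tab$tier <- "silver"
  dplyr::distinct(tibble::as_tibble(tab),
                  .data$gene_a, .data$gene_b, .data$label, .data$tier)
}

#' Write a table as TSV
#'
#' All package outputs are tab-separated with a header row so that
#' `write_tsv(read_*(x))` round-trips byte-identically.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}
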