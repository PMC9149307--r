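#' Classify scored records into activating / suppressive / unknown
#'
#' A record is called CTL-activating when it is significant (`fdr <
#' fdr_threshold`, strict inequality) with a positive score, CTL-suppressive
#' when significant with a negative score, and unknown otherwise. Works on
#' interaction-level tables and on gene-level aggregates alike; any table
#' with `z_final` and `fdr` columns qualifies.
#'
#' @param scored Table with `z_final` and `fdr` columns.
#' @param fdr_threshold FDR cutoff; default 0.05.
#' @return `scored` with a `prediction` factor column appended.
#' @export
classify_scores <- function(scored, fdr_threshold = 0.05) {
  stopifnot(all(c("z_final", "fdr") %in% names(scored)))
  pred <- dplyr::case_when(
    scored$fdr < fdr_threshold & scored$z_final > 0 ~ "activating",
    scored$fdr < fdr_threshold & scored$z_final < 0 ~ "suppressive",
    .default = "unknown"
  )
  scored$prediction <- factor(pred, levels = ic_classes())
  scored
}

ic_classes <- function() c("activating", "suppressive", "unknown")

#' Match a curated standard set against classified scores
#'
#' A standard pair matches a scored instance when the unordered gene set
#' `{ctl_gene, tnbc_gene}` equals `{gene_a, gene_b}`. When both orientations
#' of a pair were scored, the instance with the largest `|z_final|`
#' represents the pair. Scored instances matching no standard carry truth
#' `"unknown"`; standard pairs absent from the score table are excluded
#' from the confusion matrix and returned in the `unmatched` attribute.
#'
#' @param standards A standard set ([read_standards()]).
#' @param classified Output of [classify_scores()] at interaction level.
#' @return A tibble with one row per evaluated record: `gene_a`, `gene_b`,
#'   `truth`, `prediction`, `z_final`, `fdr`; attribute `unmatched` holds
#'   the standards that matched nothing.
#' @export
match_standard <- function(standards, classified) {
  if (nrow(standards) == 0 || nrow(classified) == 0) {
    stop("match_standard: empty standards or score table", call. = FALSE)
  }
  pair_key <- function(a, b) {
    purrr::map2_chr(a, b, ~ paste(sort(c(.x, .y)), collapse = "\r"))
  }
  std <- standards |>
    dplyr::mutate(key = pair_key(.data$gene_a, .data$gene_b)) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
  sc <- classified |>
    dplyr::mutate(key = pair_key(.data$ctl_gene, .data$tnbc_gene))

  in_std <- sc$key %in% std$key
  # one representative per standard pair: the orientation with max |z_final|
  matched <- sc[in_std, ] |>
    dplyr::arrange(.data$key, dplyr::desc(abs(.data$z_final))) |>
    dplyr::group_by(.data$key) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::select(std, "key", truth = "label"), by = "key")
  rest <- sc[!in_std, ] |>
    dplyr::mutate(truth = "unknown")

  out <- dplyr::bind_rows(matched, rest) |>
    dplyr::transmute(
      gene_a = .data$ctl_gene, gene_b = .data$tnbc_gene,
      truth = factor(.data$truth, levels = ic_classes()),
      prediction = .data$prediction,
      z_final = .data$z_final,
      fdr = .data$fdr
    )
  attr(out, "unmatched") <- std[!std$key %in% sc$key,
                                c("gene_a", "gene_b", "label", "tier")]
  out
}

#' Three-class confusion matrix and macro-averaged metrics
#'
#' Builds the full activating / suppressive / unknown confusion matrix and
#' per-class precision, recall and F1 for the two evaluated classes. The
#' unknown class is never evaluated in its own right -- it may contain real
#' but uncharacterized targets -- yet its members still count as false
#' positives when predicted into an evaluated class. Macro metrics are the
#' unweighted mean over the evaluated classes; in particular macro-F1 is
#' the arithmetic mean of the two class F1 scores (not the harmonic mean of
#' macro precision and macro recall). When both classes appear among the
#' truth labels and the matched standards carry scores, the activating-vs-
#' suppressive AUROC of `z_final` is computed as well.
#'
#' @param pairs Truth/prediction pairs from [match_standard()] (columns
#'   `truth`, `prediction`, optionally `z_final`).
#' @return An object of class `ic_report`: list with `confusion` (3x3
#'   matrix, rows = truth), `per_class` tibble, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `auroc` (NA when undefined), `n`.
#' @export
confusion_and_metrics <- function(pairs) {
  stopifnot(all(c("truth", "prediction") %in% names(pairs)))
  truth <- factor(pairs$truth, levels = ic_classes())
  pred <- factor(pairs$prediction, levels = ic_classes())
  confusion <- table(truth = truth, prediction = pred)

  eval_classes <- c("activating", "suppressive")
  present <- eval_classes[rowSums(confusion)[eval_classes] > 0]
  if (length(present) < length(eval_classes)) {
    warning("confusion_and_metrics: class(es) with no truth members: ",
            paste(setdiff(eval_classes, present), collapse = ", "),
            "; macro metrics averaged over the remaining class(es)",
            call. = FALSE)
  }

  per_class <- purrr::map_dfr(eval_classes, function(cl) {
    tp <- confusion[cl, cl]
    n_pred <- sum(confusion[, cl])
    n_truth <- sum(confusion[cl, ])
    precision <- if (n_pred > 0) tp / n_pred else 0
    recall <- if (n_truth > 0) tp / n_truth else NA_real_
    f1 <- if (!is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else if (!is.na(recall)) 0 else NA_real_
    tibble::tibble(class = cl, n_truth = n_truth, n_predicted = n_pred,
                   tp = as.integer(tp), precision = precision,
                   recall = recall, f1 = f1)
  })

  macro <- dplyr::filter(per_class, .data$class %in% present)
  auc <- NA_real_
  if ("z_final" %in% names(pairs) && length(present) == 2) {
    std <- pairs[pairs$truth %in% eval_classes, ]
    auc <- auroc(std$z_final, std$truth == "activating")
  }

  structure(
    list(
      confusion = confusion,
      per_class = per_class,
      macro_precision = mean(macro$precision),
      macro_recall = mean(macro$recall),
      macro_f1 = mean(macro$f1),
      auroc = auc,
      n = nrow(pairs)
    ),
    class = "ic_report"
  )
}

#' Area under the ROC curve by the rank-sum formulation
#'
#' Computes the probability that a randomly drawn positive outscores a
#' randomly drawn negative, counting ties as one half -- the Mann-Whitney
#' statistic with midranks, equivalent to trapezoidal AUROC.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return The AUROC, or `NA` when either class is empty.
#' @export
#'
#' @examples
#' auroc(c(2, 3, -1, -2), c(TRUE, TRUE, FALSE, FALSE)) # 1
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos < 1 || n_neg < 1) {
    return(NA_real_)
  }
  r <- rank(scores) # midranks for ties
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a score table against a standard set
#'
#' Convenience wrapper: [classify_scores()], [match_standard()],
#' [confusion_and_metrics()].
#'
#' @inheritParams classify_scores
#' @inheritParams match_standard
#' @return An `ic_report`.
#' @export
evaluate_scores <- function(scored, standards, fdr_threshold = 0.05) {
  scored |>
    classify_scores(fdr_threshold) |>
    (\(x) match_standard(standards, x))() |>
    confusion_and_metrics()
}

#' @export
print.ic_report <- function(x, ...) {
  cat("Intercellular screen evaluation (", x$n, " records)\n\n", sep = "")
  print(x$confusion)
  cat("\n")
  print(as.data.frame(x$per_class), row.names = FALSE, digits = 3)
  cat(sprintf("\nmacro precision %.2f | macro recall %.2f | macro F1 %.2f",
              x$macro_precision, x$macro_recall, x$macro_f1))
  if (!is.na(x$auroc)) cat(sprintf(" | AUROC %.2f", x$auroc))
  cat("\n")
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `ic_report`.
#' @param ... Unused.
#' @return Per-class metrics as a tibble.
#' @export
tidy.ic_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of an evaluation report
#'
#' @param x An `ic_report`.
#' @param ... Unused.
#' @return A one-row tibble with macro metrics, AUROC and record count.
#' @export
glance.ic_report <- function(x, ...) {
  tibble::tibble(
    macro_precision = x$macro_precision,
    macro_recall = x$macro_recall,
    macro_f1 = x$macro_f1,
    auroc = x$auroc,
    n = x$n
  )
}
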