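#' Rescale sample columns of a guide-count table to a common library size
#'
#' Each sample column is multiplied by a scalar so that its column sum equals
#' `target_total`. Pooled-screen counts are compared between samples as
#' fold changes, so columns must be on a common scale before any ratio is
#' taken; matrices that are already normalized pass through unchanged when
#' `target_total` equals their column sums.
#'
#' @param counts A data frame with columns `guide_id`, `gene_id` and one
#'   numeric column per sample.
#' @param target_total Total count each sample column is scaled to.
#'   Default 1e7 reads, the convention of the drugZ differential-analysis
#'   algorithm this package follows.
#'
#' @return A tibble of the same shape with scaled sample columns.
#' @export
#'
#' @examples
#' counts <- tibble::tibble(
#'   guide_id = c("g1", "g2"), gene_id = c("A", "B"),
#'   s1 = c(40, 60), s2 = c(30, 170)
#' )
#' normalize_counts(counts, target_total = 100)
normalize_counts <- function(counts, target_total = 1e7) {
  stopifnot(target_total > 0)
  counts <- validate_guide_counts(counts)
  sample_cols <- guide_sample_cols(counts)
  sums <- vapply(counts[sample_cols], sum, numeric(1))
  if (any(sums <= 0)) {
    stop("normalize_counts: sample column(s) with zero total count: ",
         paste(sample_cols[sums <= 0], collapse = ", "), call. = FALSE)
  }
  counts[sample_cols] <- purrr::map2(counts[sample_cols], sums,
                                     ~ .x * (target_total / .y))
  counts
}

#' Guide-level z-scores by the empirical-Bayes fold-change procedure
#'
#' For every treatment/control sample pairing, computes the log2 fold change
#' of each guide, `log2((treatment + pseudocount) / (control + pseudocount))`,
#' and standardizes it into a z-score. The standard deviation of a guide's
#' fold change is not estimated from that guide alone: guides are ranked by
#' their control-sample count and each guide borrows the fold changes of the
#' guides within `half_window` ranks on either side (the window is truncated
#' at the top and bottom of the ranking). This empirical-Bayes pooling
#' stabilizes the variance estimate for low-count guides, whose fold changes
#' are intrinsically noisier.
#'
#' Pairing rule: when the number of treatment and control samples is equal,
#' treatment sample i is paired with control sample i; otherwise every
#' treatment sample is paired against the mean of the control samples.
#'
#' @param counts Guide-count table (`guide_id`, `gene_id`, sample columns).
#' @param treatment,control Character vectors of sample column names.
#' @param pseudocount Added to both counts before the ratio; default 5.
#' @param half_window Number of ranks on either side contributing to the
#'   standard-deviation estimate; default 500. If the library holds fewer
#'   than `2 * half_window + 1` guides the window covers all guides and a
#'   warning is emitted.
#' @param sd_floor Lower clamp on the estimated standard deviation
#'   (log2 units); prevents infinite z-scores on degenerate windows.
#'
#' @return A tibble with one row per guide per pairing: `guide_id`,
#'   `gene_id`, `pairing`, `control_mean`, `fold_change`, `z`.
#' @export
guide_zscores <- function(counts, treatment, control,
                          pseudocount = 5, half_window = 500,
                          sd_floor = 1e-3) {
  stopifnot(pseudocount > 0, half_window >= 1)
  counts <- validate_guide_counts(counts)
  sample_cols <- guide_sample_cols(counts)
  missing <- setdiff(c(treatment, control), sample_cols)
  if (length(missing) > 0) {
    stop("guide_zscores: sample(s) not found in count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(treatment) < 1 || length(control) < 1) {
    stop("guide_zscores: need at least one treatment and one control sample",
         call. = FALSE)
  }

  n_guides <- nrow(counts)
  if (n_guides < 2 * half_window + 1) {
    warning("guide_zscores: ", n_guides, " guides < window size ",
            2 * half_window + 1, "; using all guides in every window",
            call. = FALSE)
  }

  paired <- length(treatment) == length(control)
  pairings <- if (paired) {
    purrr::map2(treatment, control,
                ~ list(trt = counts[[.x]], ctl = counts[[.y]],
                       label = paste0(.x, "_vs_", .y)))
  } else {
    ctl_mean <- rowMeans(counts[control])
    purrr::map(treatment,
               ~ list(trt = counts[[.x]], ctl = ctl_mean,
                      label = paste0(.x, "_vs_ctrl_mean")))
  }

  purrr::map_dfr(pairings, function(p) {
    fc <- log2((p$trt + pseudocount) / (p$ctl + pseudocount))
    # rank guides by control count, highest first; window sd in rank space
    ord <- order(p$ctl, decreasing = TRUE)
    sd_ranked <- rolling_sd(fc[ord], half_window)
    sds <- numeric(n_guides)
    sds[ord] <- pmax(sd_ranked, sd_floor)
    tibble::tibble(
      guide_id = counts$guide_id,
      gene_id = counts$gene_id,
      pairing = p$label,
      control_mean = p$ctl,
      fold_change = fc,
      z = fc / sds
    )
  })
}

# Rolling standard deviation over windows [i - hw, i + hw] in an ordered
# vector, truncated at the boundaries; O(n) via cumulative sums.
rolling_sd <- function(x, hw) {
  n <- length(x)
  if (n < 2 * hw + 1) {
    return(rep(sd(x), n))
  }
  lo <- pmax(1L, seq_len(n) - hw)
  hi <- pmin(n, seq_len(n) + hw)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  s1 <- cs[hi] - c(0, cs)[lo]
  s2 <- cs2[hi] - c(0, cs2)[lo]
  m <- hi - lo + 1
  v <- (s2 - s1^2 / m) / (m - 1)
  sqrt(pmax(v, 0))
}

#' Collapse guide-level z-scores into a per-gene normZ statistic
#'
#' The normZ score of a gene is the sum of the z-scores of all guide-level
#' observations targeting it (guides times treatment/control pairings)
#' divided by the square root of their number. Because each z-score is
#' approximately standard normal under the null, the Stouffer divisor keeps
#' normZ standard normal as well, which is what later lets interaction-level
#' p-values be read off the normal tail.
#'
#' @param guide_z Output of [guide_zscores()].
#' @param screen_id Identifier recorded in the `screen_id` column.
#'
#' @return A tibble: `screen_id`, `gene_id`, `normZ`, `n_obs` (z entries
#'   summed), `n_guides` (distinct guides).
#' @export
gene_normz <- function(guide_z, screen_id = "screen") {
  stopifnot(all(c("guide_id", "gene_id", "z") %in% names(guide_z)))
  if (any(!is.finite(guide_z$z))) {
    stop("gene_normz: non-finite guide z-scores", call. = FALSE)
  }
  guide_z |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      normZ = sum(.data$z) / sqrt(dplyr::n()),
      n_obs = dplyr::n(),
      n_guides = dplyr::n_distinct(.data$guide_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(screen_id = screen_id, .before = 1)
}

#' Orient a screen so that positive normZ means CTL-activating
#'
#' Downstream combination assumes a shared sign convention: positive scores
#' mark genes whose normal function activates cytotoxic T lymphocytes
#' (CTLs), negative scores mark CTL-suppressive genes. A cancer-cell screen
#' contrasting co-culture against monoculture and an immune-cell screen
#' contrasting library against tumor already satisfy this
#' (`"treatment_enriched_is_positive"`); a dataset computed in the opposite
#' direction is flipped (`"control_enriched_is_positive"`).
#'
#' @param gene_scores A gene normZ table from [gene_normz()].
#' @param orientation `"treatment_enriched_is_positive"` (identity) or
#'   `"control_enriched_is_positive"` (negate all scores).
#'
#' @return The table with `normZ` signs adjusted.
#' @export
orient_screen <- function(gene_scores,
                          orientation = c("treatment_enriched_is_positive",
                                          "control_enriched_is_positive")) {
  orientation <- match.arg(orientation)
  if (orientation == "control_enriched_is_positive") {
    gene_scores <- dplyr::mutate(gene_scores, normZ = -.data$normZ)
  }
  gene_scores
}

#' One-call differential analysis for a single screen
#'
#' Runs [normalize_counts()] (optional), [guide_zscores()], [gene_normz()]
#' and [orient_screen()] in sequence.
#'
#' @inheritParams guide_zscores
#' @inheritParams orient_screen
#' @param screen_id Identifier for the output table.
#' @param normalize Whether to rescale columns to `target_total` first.
#' @param target_total Library size used when `normalize = TRUE`.
#'
#' @return A gene normZ tibble (see [gene_normz()]).
#' @export
screen_normz <- function(counts, treatment, control, screen_id = "screen",
                         orientation = "treatment_enriched_is_positive",
                         normalize = TRUE, target_total = 1e7,
                         pseudocount = 5, half_window = 500,
                         sd_floor = 1e-3) {
  if (normalize) counts <- normalize_counts(counts, target_total)
  counts |>
    guide_zscores(treatment, control, pseudocount = pseudocount,
                  half_window = half_window, sd_floor = sd_floor) |>
    gene_normz(screen_id = screen_id) |>
    orient_screen(orientation)
}
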