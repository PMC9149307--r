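#' Assemble and validate a run configuration
#'
#' A run configuration names the screens (count file, sample roles,
#' orientation, whether the screen is the immune-cell one or a cancer cell
#' line), the expression inputs, the ligand-receptor catalog, an optional
#' standard set, and the scoring thresholds. [read_run_config()] loads the
#' same structure from a YAML file.
#'
#' @param screens A list of screen specs; each a list with `id`, `role`
#'   (`"ctl"` or `"tnbc"`), `path` (guide-count TSV), `treatment`,
#'   `control` (sample name vectors), and optional `orientation`.
#' @param catalog Path to the catalog TSV.
#' @param expression_calls Optional path to a long expression-call TSV.
#' @param expression_tables Optional list of specs `list(context =, path =)`
#'   pointing at bulk FPKM tables, thresholded at `fpkm_threshold`.
#' @param gene_lists Optional list of specs `list(context =, path =)`
#'   pointing at expressed-gene list files.
#' @param standards Optional path to a standards TSV.
#' @param ctl_context Context label of the immune cells in the expression
#'   calls; default `"CTL"`.
#' @param method Scoring method: `"tolerant"` (default), `"strict"` or
#'   `"composite"`.
#' @param fdr_threshold,abs_z_threshold,fpkm_threshold Thresholds for
#'   classification, shortlisting and expression calling.
#' @param normalize,target_total,pseudocount,half_window Differential-
#'   analysis settings (see [guide_zscores()]).
#' @param seed Integer seed recorded with the run.
#'
#' @return A list of class `ic_run_config`.
#' @export
run_config <- function(screens, catalog,
                       expression_calls = NULL, expression_tables = NULL,
                       gene_lists = NULL, standards = NULL,
                       ctl_context = "CTL",
                       method = c("tolerant", "strict", "composite"),
                       fdr_threshold = 0.05, abs_z_threshold = 3,
                       fpkm_threshold = 10,
                       normalize = TRUE, target_total = 1e7,
                       pseudocount = 5, half_window = 500, seed = 1L) {
  method <- match.arg(method)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  roles <- vapply(screens, function(s) s$role %||% "tnbc", character(1))
  if (sum(roles == "ctl") != 1) {
    stop("run_config: exactly one screen must have role 'ctl'",
         call. = FALSE)
  }
  for (s in screens) {
    if (length(s$treatment) < 1 || length(s$control) < 1) {
      stop("run_config: screen '", s$id,
           "' needs >=1 treatment and >=1 control sample", call. = FALSE)
    }
  }
  structure(as.list(environment())[setdiff(names(formals(run_config)),
                                           "...")],
            class = "ic_run_config")
}

#' @param path Path to a YAML file mirroring the [run_config()] fields.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Run the full intercellular screen pipeline
#'
#' Differential analysis per screen, expression gating, oriented
#' ligand-receptor scoring with per-direction FDR, gene-level aggregation,
#' candidate shortlisting, and (when a standard set is configured)
#' three-class evaluation. Record counts are logged at every stage. When
#' `outdir` is given, each result table is also written as TSV.
#'
#' @param config An `ic_run_config` (or path to its YAML file).
#' @param outdir Optional output directory for the result TSVs.
#' @return A list of class `ic_run`: `screens` (oriented gene normZ, one
#'   tibble per screen), `calls`, `scores`, `gene_level_ctl`,
#'   `gene_level_tnbc`, `shortlist`, `report` (`ic_report` or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "ic_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  screens <- stage("diffanalysis", {
    purrr::map(config$screens, function(s) {
      counts <- read_guide_counts(s$path, s$treatment, s$control)
      tab <- screen_normz(
        counts, s$treatment, s$control, screen_id = s$id,
        orientation = s$orientation %||% "treatment_enriched_is_positive",
        normalize = config$normalize, target_total = config$target_total,
        pseudocount = config$pseudocount, half_window = config$half_window
      )
      message("diffanalysis[", s$id, "]: ", nrow(counts), " guides -> ",
              nrow(tab), " genes")
      tab
    }) |>
      setNames(vapply(config$screens, `[[`, character(1), "id"))
  })

  calls <- stage("expression_gate", {
    parts <- list()
    if (!is.null(config$expression_calls)) {
      parts <- c(parts, list(read_expression_calls(config$expression_calls)))
    }
    for (spec in config$expression_tables %||% list()) {
      parts <- c(parts, list(
        call_expressed(read_expression_table(spec$path), spec$context,
                       threshold = config$fpkm_threshold)))
    }
    for (spec in config$gene_lists %||% list()) {
      parts <- c(parts, list(read_gene_list(spec$path, spec$context)))
    }
    if (length(parts) == 0) {
      stop("no expression input configured", call. = FALSE)
    }
    dplyr::bind_rows(parts)
  })

  roles <- vapply(config$screens, function(s) s$role %||% "tnbc",
                  character(1))
  ctl_id <- config$screens[[which(roles == "ctl")]]$id
  tnbc_ids <- vapply(config$screens[roles == "tnbc"], `[[`, character(1),
                     "id")

  gated_ctl <- stage("expression_gate",
                     gate_scores(screens[[ctl_id]], calls,
                                 config$ctl_context))
  gated_tnbc <- stage("expression_gate", {
    purrr::map_dfr(tnbc_ids, function(id) {
      gate_scores(screens[[id]], calls, id) |>
        dplyr::mutate(cell_line = id)
    })
  })

  scores <- stage("interaction_scoring", {
    catalog <- read_catalog(config$catalog)
    message("catalog: ", nrow(catalog), " ordered pairs (",
            attr(catalog, "n_unordered"), " unordered)")
    enumerate_oriented(catalog) |>
      score_interactions(gated_ctl, gated_tnbc, method = config$method) |>
      scores_to_significance() |>
      dplyr::arrange(dplyr::desc(abs(.data$z_final)))
  })

  shortlist <- stage("interaction_scoring",
                     shortlist_candidates(scores, calls,
                                          ctl_context = config$ctl_context,
                                          fdr_threshold = config$fdr_threshold,
                                          abs_z_threshold =
                                            config$abs_z_threshold))
  gl_ctl <- gene_level_aggregate(scores, "ctl")
  gl_tnbc <- gene_level_aggregate(scores, "tnbc")

  report <- NULL
  if (!is.null(config$standards)) {
    report <- stage("evaluation", {
      standards <- read_standards(config$standards)
      if (nrow(standards) > 0) {
        evaluate_scores(scores, standards, config$fdr_threshold)
      } else NULL
    })
  }

  out <- structure(
    list(screens = screens, calls = calls, scores = scores,
         gene_level_ctl = gl_ctl, gene_level_tnbc = gl_tnbc,
         shortlist = shortlist, report = report, config = config),
    class = "ic_run"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(screens)) {
      write_tsv(screens[[id]], file.path(outdir,
                                         paste0("normz_", id, ".tsv")))
    }
    write_tsv(scores, file.path(outdir, "interaction_scores.tsv"))
    write_tsv(shortlist, file.path(outdir, "shortlist.tsv"))
    write_tsv(gl_ctl, file.path(outdir, "gene_level_ctl.tsv"))
    write_tsv(gl_tnbc, file.path(outdir, "gene_level_tnbc.tsv"))
    if (!is.null(report)) {
      write_tsv(tidy(report), file.path(outdir, "evaluation_per_class.tsv"))
      write_tsv(glance(report), file.path(outdir, "evaluation_summary.tsv"))
    }
  }
  out
}

#' @export
print.ic_run <- function(x, ...) {
  cat("Intercellular CRISPR screen run (method: ", x$config$method, ")\n",
      sep = "")
  cat("  screens: ", paste(names(x$screens), collapse = ", "), "\n", sep = "")
  cat("  scored instances: ", nrow(x$scores), "\n", sep = "")
  cat("  shortlisted candidates: ", nrow(x$shortlist), "\n", sep = "")
  if (!is.null(x$report)) {
    cat(sprintf("  evaluation: macro P %.2f / R %.2f / F1 %.2f\n",
                x$report$macro_precision, x$report$macro_recall,
                x$report$macro_f1))
  }
  invisible(x)
}
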