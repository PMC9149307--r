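#' Configuration for the synthetic screen universe
#'
#' Bundles every knob of the simulator. Defaults describe a small but
#' realistic pooled-screen study: 2000 genes with 4 guides each, two
#' treatment and two control samples per screen, negative-binomial counts
#' around a log-normally heterogeneous per-guide baseline of 500 reads,
#' planted knockout effects of 2 log2 units, 5% of genes CTL-activating
#' and 5% CTL-suppressive, two cancer cell lines, a 400-pair
#' ligand-receptor catalog of which 10% are planted concordant (these form
#' the standard set), and 30% of genes unexpressed per cancer context.
#'
#' @param n_genes Number of genes per screen.
#' @param guides_per_gene Guides targeting each gene.
#' @param n_treatment,n_control Samples per role.
#' @param baseline_mean Median per-guide control count.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param effect_log2fc Planted knockout effect size, log2 units.
#' @param frac_activating,frac_suppressive Fractions of genes planted in
#'   each class (must sum to at most 1).
#' @param cell_lines Names of the simulated cancer cell lines.
#' @param n_pairs Catalog size (ordered ligand-receptor pairs).
#' @param frac_concordant_pairs Fraction of catalog pairs planted with both
#'   members in the same class; these become the standard set.
#' @param fpkm_threshold Expression cutoff used when drawing FPKM values.
#' @param frac_unexpressed Fraction of genes drawn unexpressed per cancer
#'   cell context.
#' @param seed Base seed; all draws derive from it by fixed offsets
#'   (truth table +0, CTL screen +1, cell line k +1+k, universe +100), so
#'   a run is fully reproducible from the single integer.
#'
#' @return A list of class `ic_sim_config`.
#' @export
sim_config <- function(n_genes = 2000, guides_per_gene = 4,
                       n_treatment = 2, n_control = 2,
                       baseline_mean = 500, dispersion = 0.1,
                       effect_log2fc = 2,
                       frac_activating = 0.05, frac_suppressive = 0.05,
                       cell_lines = c("lineA", "lineB"),
                       n_pairs = 400, frac_concordant_pairs = 0.1,
                       fpkm_threshold = 10, frac_unexpressed = 0.3,
                       seed = 1L) {
  stopifnot(
    n_genes >= 2, guides_per_gene >= 1, n_treatment >= 1, n_control >= 1,
    baseline_mean > 0, dispersion > 0,
    frac_activating >= 0, frac_suppressive >= 0,
    frac_activating + frac_suppressive <= 1,
    length(cell_lines) >= 1, n_pairs >= 1,
    frac_concordant_pairs >= 0, frac_concordant_pairs <= 1,
    fpkm_threshold >= 0, frac_unexpressed >= 0, frac_unexpressed <= 1
  )
  structure(as.list(environment()), class = "ic_sim_config")
}

#' Planted per-gene truth classes
#'
#' Assigns each gene a class -- `activating`, `suppressive` or `null` --
#' with the configured fractions, identically for every screen drawn from
#' the same config (classes are a property of the gene, not of a screen).
#'
#' @param config An [sim_config()].
#' @return A tibble `gene_id`, `class`.
#' @export
sim_gene_truth <- function(config) {
  stopifnot(inherits(config, "ic_sim_config"))
  set.seed(config$seed)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  n_act <- round(config$frac_activating * config$n_genes)
  n_sup <- round(config$frac_suppressive * config$n_genes)
  cls <- sample(c(rep("activating", n_act), rep("suppressive", n_sup),
                  rep("null", config$n_genes - n_act - n_sup)))
  tibble::tibble(gene_id = genes, class = cls)
}

#' Simulate one pooled CRISPR screen
#'
#' Per guide, a baseline mean is drawn log-normally around
#' `baseline_mean` (sdlog 1, emulating the wide coverage heterogeneity of
#' pooled libraries); control counts are negative binomial around it, and
#' treatment counts are negative binomial around
#' `baseline * 2^(s * effect_log2fc)` where `s` is +1 for planted
#' activating genes, -1 for suppressive genes and 0 for nulls. Counts are
#' emitted raw; the screen is therefore analysed with
#' `normalize = TRUE`. The sign convention matches
#' `"treatment_enriched_is_positive"`: after differential analysis,
#' activating genes come out positive with no flip.
#'
#' @param config An [sim_config()].
#' @param role `"ctl"` for the immune-cell screen or the name of a cancer
#'   cell line from `config$cell_lines`; only the derived seed differs, so
#'   screens share planted classes but have independent noise.
#'
#' @return A list with `counts` (guide-count tibble with samples
#'   `trt1..`, `ctl1..`) and `truth` (the gene class table).
#' @export
simulate_screen <- function(config, role = "ctl") {
  stopifnot(inherits(config, "ic_sim_config"))
  truth <- sim_gene_truth(config)
  offset <- if (identical(role, "ctl")) 1L else {
    k <- match(role, config$cell_lines)
    if (is.na(k)) stop("simulate_screen: unknown role '", role, "'",
                       call. = FALSE)
    1L + k
  }
  set.seed(config$seed + offset)

  n_guides <- config$n_genes * config$guides_per_gene
  gene_id <- rep(truth$gene_id, each = config$guides_per_gene)
  s <- rep(dplyr::case_match(truth$class, "activating" ~ 1,
                             "suppressive" ~ -1, "null" ~ 0),
           each = config$guides_per_gene)
  baseline <- rlnorm(n_guides, meanlog = log(config$baseline_mean), sdlog = 1)
  mu_trt <- baseline * 2^(s * config$effect_log2fc)
  size <- 1 / config$dispersion

  counts <- tibble::tibble(
    guide_id = sprintf("%s_g%d", gene_id,
                       rep(seq_len(config$guides_per_gene), config$n_genes)),
    gene_id = gene_id
  )
  for (j in seq_len(config$n_treatment)) {
    counts[[paste0("trt", j)]] <- as.numeric(
      rnbinom(n_guides, mu = mu_trt, size = size))
  }
  for (j in seq_len(config$n_control)) {
    counts[[paste0("ctl", j)]] <- as.numeric(
      rnbinom(n_guides, mu = baseline, size = size))
  }
  list(counts = counts, truth = truth)
}

#' Simulate the interaction universe: catalog, expression calls, standards
#'
#' Draws `n_pairs` ordered ligand-receptor pairs over the gene universe.
#' A planted fraction of pairs is concordant -- both members drawn from the
#' same non-null class -- and these pairs, labeled with that class, form
#' the standard set; the remaining pairs pair up null genes. Expression
#' calls are generated for the CTL context and each cancer cell line:
#' a configured fraction of genes per cancer context is drawn unexpressed
#' (FPKM uniform below the threshold), the rest above it. To exercise the
#' one-side-unexpressed mechanism, the cancer-side gene of the first
#' planted standard pair is forced unexpressed in every cancer context
#' while remaining expressed in CTLs (the way an immune-checkpoint ligand
#' can be missing from particular tumor lines yet discoverable through its
#' receptor on the T cell).
#'
#' @param config An [sim_config()].
#' @return A list with `catalog`, `expression` (calls for all contexts,
#'   long), and `standards`.
#' @export
simulate_universe <- function(config) {
  stopifnot(inherits(config, "ic_sim_config"))
  truth <- sim_gene_truth(config)
  set.seed(config$seed + 100L)

  n_conc <- round(config$n_pairs * config$frac_concordant_pairs)
  classes <- split(truth$gene_id, truth$class)
  act <- classes[["activating"]] %||% character(0)
  sup <- classes[["suppressive"]] %||% character(0)
  nul <- classes[["null"]] %||% truth$gene_id

  conc_class <- sample(c("activating", "suppressive"), n_conc,
                       replace = TRUE,
                       prob = c(length(act), length(sup)) + 1e-9)
  draw_pair <- function(pool) sample(pool, 2, replace = FALSE)
  conc <- purrr::map(conc_class, function(cl) {
    draw_pair(if (cl == "activating") act else sup)
  })
  n_null_pairs <- config$n_pairs - n_conc
  null_pairs <- purrr::map(seq_len(n_null_pairs), ~ draw_pair(nul))

  catalog <- tibble::tibble(
    ligand_gene = c(purrr::map_chr(conc, 1), purrr::map_chr(null_pairs, 1)),
    receptor_gene = c(purrr::map_chr(conc, 2), purrr::map_chr(null_pairs, 2)),
    source = "simulated"
  ) |>
    dplyr::distinct(.data$ligand_gene, .data$receptor_gene,
                    .keep_all = TRUE)

  standards <- tibble::tibble(
    gene_a = purrr::map_chr(conc, 1),
    gene_b = purrr::map_chr(conc, 2),
    label = conc_class,
    tier = "silver"
  ) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)

  draw_calls <- function(context, frac_off) {
    off <- runif(config$n_genes) < frac_off
    fpkm <- ifelse(off,
                   runif(config$n_genes, 0, config$fpkm_threshold * 0.99),
                   config$fpkm_threshold *
                     exp(runif(config$n_genes, 0.01, 4)))
    tibble::tibble(context = context, gene_id = truth$gene_id,
                   mean_expression = fpkm,
                   expressed = fpkm >= config$fpkm_threshold)
  }
  expression <- dplyr::bind_rows(
    draw_calls("CTL", 0),
    purrr::map_dfr(config$cell_lines,
                   ~ draw_calls(.x, config$frac_unexpressed))
  )

  if (nrow(standards) > 0 && config$frac_unexpressed > 0) {
    gated_gene <- standards$gene_b[1]
    expression <- expression |>
      dplyr::mutate(
        off = .data$context %in% config$cell_lines &
          .data$gene_id == gated_gene,
        mean_expression = dplyr::if_else(
          .data$off, config$fpkm_threshold / 2, .data$mean_expression),
        expressed = dplyr::if_else(.data$off, FALSE, .data$expressed)
      ) |>
      dplyr::select(-"off")
  }

  list(catalog = catalog, expression = expression, standards = standards)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a complete simulated run directory
#'
#' Emits every input the pipeline consumes -- one guide-count TSV per
#' screen, expression-call TSV, catalog TSV, standards TSV, truth TSV and
#' a ready-to-run YAML config -- in the exact dialects the readers expect.
#'
#' @param config An [sim_config()].
#' @param dir Output directory (created if needed).
#' @return The path of the written YAML config, invisibly.
#' @export
simulate_run <- function(config, dir) {
  stopifnot(inherits(config, "ic_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  screens <- c("ctl", config$cell_lines)
  screen_specs <- purrr::map(screens, function(role) {
    sim <- simulate_screen(config, role)
    path <- file.path(dir, paste0("counts_", role, ".tsv"))
    write_tsv(sim$counts, path)
    list(id = role,
         role = if (role == "ctl") "ctl" else "tnbc",
         path = path,
         treatment = paste0("trt", seq_len(config$n_treatment)),
         control = paste0("ctl", seq_len(config$n_control)),
         orientation = "treatment_enriched_is_positive")
  })
  uni <- simulate_universe(config)
  write_tsv(uni$catalog, file.path(dir, "catalog.tsv"))
  write_tsv(uni$expression, file.path(dir, "expression_calls.tsv"))
  write_tsv(uni$standards, file.path(dir, "standards.tsv"))
  write_tsv(sim_gene_truth(config), file.path(dir, "gene_truth.tsv"))

  cfg <- list(
    screens = screen_specs,
    expression_calls = file.path(dir, "expression_calls.tsv"),
    ctl_context = "CTL",
    catalog = file.path(dir, "catalog.tsv"),
    standards = file.path(dir, "standards.tsv"),
    method = "tolerant",
    fdr_threshold = 0.05,
    abs_z_threshold = 3,
    fpkm_threshold = config$fpkm_threshold,
    seed = config$seed
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
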