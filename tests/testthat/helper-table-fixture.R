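# Shortlist rows of the published case study: gene-level normZ inputs of
# seven candidate interactions and the final Tolerant scores they combine
# to. The cancer-side partner of the Slc7a1 row is unexpressed in both
# cell lines, so its screen scores are gated to zero and the final score
# collapses onto the CTL side.
shortlist_fixture <- function() {
  tibble::tibble(
    ctl_gene = c("Itgav", "Lta", "Ltb", "Lta", "Gm49339", "Slc7a1", "Sdc2"),
    tnbc_gene = c("Calr", "Tnfrsf1a", "Tnfrsf1a", "Tnfrsf1b", "Bst2",
                  "Ccl4", "Fn1"),
    z_ctl = c(1.33, 1.19, 0.51, 1.19, -2.72, -3.28, -2.52),
    z_4T1 = c(4.28, 2.49, 2.49, 0.96, -0.88, 0.36, -0.91),
    z_EMT6 = c(3.81, 5.05, 5.05, 4.74, -1.04, -0.02, -0.42),
    expressed_4T1 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    expressed_EMT6 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    z_final_published = c(5.375, 4.96, 4.28, 4.04, -3.68, -3.28, -3.185)
  )
}

# Run the fixture through the real gate + scoring path and return the
# final Tolerant score per row.
score_shortlist_fixture <- function() {
  fx <- shortlist_fixture()
  ctl_scores <- tibble::tibble(gene_id = fx$ctl_gene, normZ = fx$z_ctl)
  tnbc_raw <- dplyr::bind_rows(
    tibble::tibble(screen_id = "4T1", gene_id = fx$tnbc_gene,
                   normZ = fx$z_4T1),
    tibble::tibble(screen_id = "EMT6", gene_id = fx$tnbc_gene,
                   normZ = fx$z_EMT6)
  )
  calls <- dplyr::bind_rows(
    tibble::tibble(context = "CTL", gene_id = fx$ctl_gene,
                   mean_expression = NA_real_, expressed = TRUE),
    tibble::tibble(context = "4T1", gene_id = fx$tnbc_gene,
                   mean_expression = NA_real_,
                   expressed = fx$expressed_4T1),
    tibble::tibble(context = "EMT6", gene_id = fx$tnbc_gene,
                   mean_expression = NA_real_,
                   expressed = fx$expressed_EMT6)
  )
  gated_tnbc <- purrr::map_dfr(c("4T1", "EMT6"), function(line) {
    suppressMessages(
      gate_scores(tnbc_raw[tnbc_raw$screen_id == line, ], calls, line)) |>
      dplyr::mutate(cell_line = line)
  })
  catalog <- tibble::tibble(ligand_gene = fx$ctl_gene,
                            receptor_gene = fx$tnbc_gene,
                            source = "fixture")
  oriented <- enumerate_oriented(catalog)
  oriented <- oriented[oriented$ctl_role == "ligand", ]
  scored <- suppressMessages(
    score_interactions(oriented, ctl_scores, gated_tnbc, "tolerant") |>
      scores_to_significance()
  )
  dplyr::left_join(fx, scored, by = c("ctl_gene", "tnbc_gene"))
}
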