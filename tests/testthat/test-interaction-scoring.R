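test_that("oriented enumeration emits both directions, self-pairs once", {
  cat <- tibble::tibble(ligand_gene = c("A", "C"),
                        receptor_gene = c("B", "C"),
                        source = NA_character_)
  inst <- enumerate_oriented(cat)
  expect_equal(nrow(inst), 3) # A-B both ways, C-C once
  expect_equal(sum(inst$ctl_role == "ligand"), 2)

  set.seed(5)
  genes <- paste0("g", 1:15)
  cat20 <- tibble::tibble(ligand_gene = sample(genes, 20, replace = TRUE),
                          receptor_gene = sample(genes, 20, replace = TRUE)) |>
    dplyr::distinct()
  inst20 <- enumerate_oriented(cat20)
  # brute-force: 2 per heterodimer pair, 1 per self-pair
  want <- sum(ifelse(cat20$ligand_gene == cat20$receptor_gene, 1, 2))
  expect_equal(nrow(inst20), want)
})

test_that("two-score Stouffer combination honors the sign rules", {
  expect_equal(combine_two(0, 0, "tolerant"), 0)
  expect_equal(combine_two(0, 0, "strict"), 0)
  expect_equal(combine_two(1.5, -2.0, "strict"), 0)
  expect_equal(combine_two(1.5, -2.0, "tolerant"), -0.5 / sqrt(2))
  expect_equal(combine_two(1.5, -2.0, "tolerant"), -0.35355, tolerance = 1e-4)
  # a zero never vetoes under strict
  expect_equal(combine_two(0, -2.0, "strict"), -2.0 / sqrt(2))
  expect_equal(combine_two(3, 1, "strict"), 4 / sqrt(2))
})

test_that("strict across-line combination zeroes cell-line disagreement", {
  oriented <- tibble::tibble(ctl_gene = "L", tnbc_gene = "R",
                             ctl_role = "ligand",
                             ligand_gene = "L", receptor_gene = "R")
  ctl <- tibble::tibble(gene_id = "L", normZ = 1.0)
  tnbc <- make_tnbc_scores(c("l1", "l2"), "R", list(2.0, -2.0))
  strict <- suppressMessages(
    score_interactions(oriented, ctl, tnbc, "strict"))
  expect_equal(strict$z_final, 0) # pair scores disagree across lines
  composite <- suppressMessages(
    score_interactions(oriented, ctl, tnbc, "composite"))
  expect_equal(composite$z_final,
               (combine_two(1, 2, "strict") + combine_two(1, -2, "strict")) /
                 sqrt(2))
})

test_that("significance: one-sided p, per-direction BH, order invariance", {
  tab <- tibble::tibble(ctl_gene = paste0("g", 1:4),
                        tnbc_gene = paste0("h", 1:4),
                        z_final = c(0, 3.0, 2.0, 0.1))
  out <- scores_to_significance(tab)
  expect_equal(out$p[1], 0.5)

  # hand-computed BH within the positive direction (all four are >= 0)
  p <- pnorm(-c(0, 3.0, 2.0, 0.1))
  expect_equal(out$fdr, brute_bh(p))

  # the three-score positive example against hand BH
  tab3 <- tibble::tibble(ctl_gene = "a", tnbc_gene = "b",
                         z_final = c(3.0, 2.0, 0.1))
  out3 <- scores_to_significance(tab3)
  expect_equal(out3$p, c(0.00135, 0.02275, 0.46017), tolerance = 1e-4)
  expect_equal(out3$fdr, brute_bh(out3$p))

  # mixed signs: BH runs within each tail separately
  set.seed(21)
  mix <- tibble::tibble(ctl_gene = "a", tnbc_gene = "b",
                        z_final = rnorm(50))
  m <- scores_to_significance(mix)
  pos <- m$z_final >= 0
  expect_equal(m$fdr[pos], brute_bh(m$p[pos]))
  expect_equal(m$fdr[!pos], brute_bh(m$p[!pos]))

  # permuting rows leaves each instance's fdr unchanged
  perm <- sample(nrow(mix))
  m2 <- scores_to_significance(mix[perm, ])
  expect_equal(m2$fdr[order(perm)], m$fdr)

  expect_error(scores_to_significance(mix[0, ]), "empty")
})

test_that("gene-level aggregation picks max |z| and matches the scan oracle", {
  tab <- tibble::tibble(
    ctl_gene = c("A", "A", "B"),
    tnbc_gene = c("x", "y", "x"),
    z_final = c(2.0, -3.1, 1.0)
  )
  agg <- gene_level_aggregate(tab, "ctl")
  expect_equal(agg$z_final[agg$gene_id == "A"], -3.1)
  expect_equal(agg$z_final[agg$gene_id == "B"], 1.0)

  set.seed(31)
  big <- tibble::tibble(
    ctl_gene = sample(paste0("g", 1:50), 120, replace = TRUE),
    tnbc_gene = sample(paste0("h", 1:40), 120, replace = TRUE),
    z_final = round(rnorm(120), 2)
  )
  for (side in c("ctl", "tnbc")) {
    cols <- if (side == "ctl") c("ctl_gene", "tnbc_gene") else
      c("tnbc_gene", "ctl_gene")
    got <- gene_level_aggregate(big, side)
    want <- brute_aggregate(as.data.frame(big), cols[1], cols[2])
    got <- got[order(got$gene_id), ]
    want <- want[order(want$gene_id), ]
    expect_equal(got$partner, want$partner)
    expect_equal(got$z_final, want$z_final)
  }
})

test_that("shortlisting keeps significant-or-large concordant CTL-expressed", {
  # a large negative instance collapsed onto the CTL side survives even
  # with an unremarkable FDR, because |z| clears the magnitude branch
  tab <- tibble::tibble(
    ctl_gene = c("Slc7a1", "up", "down"),
    tnbc_gene = c("Ccl4", "r1", "r2"),
    z_ctl = c(-3.28, 2.0, 1.0),
    z_tnbc_l1 = c(0, 1.5, -2.0),
    z_tnbc_l2 = c(0, 1.0, -2.0),
    z_final = c(-3.28, 3.18, -2.1),
    fdr = c(0.313, 0.01, 0.01)
  )
  calls <- make_calls("CTL", c("Slc7a1", "up", "down"))
  kept <- suppressMessages(
    shortlist_candidates(tab, calls, fdr_threshold = 0.05,
                         abs_z_threshold = 3))
  expect_setequal(kept$ctl_gene, c("Slc7a1", "up"))
  # "down" is significant but discordant (positive CTL, negative lines)

  # CTL expression requirement: same table, Slc7a1 silent in CTLs
  calls2 <- make_calls("CTL", c("Slc7a1", "up", "down"),
                       expressed = c(FALSE, TRUE, TRUE))
  kept2 <- suppressMessages(shortlist_candidates(tab, calls2))
  expect_setequal(kept2$ctl_gene, "up")

  # 30-instance random fixture against the rule-by-rule oracle
  set.seed(77)
  rnd <- tibble::tibble(
    ctl_gene = paste0("c", 1:30),
    tnbc_gene = paste0("t", 1:30),
    z_ctl = round(rnorm(30), 1) * sample(0:1, 30, TRUE),
    z_tnbc_l1 = round(rnorm(30), 1) * sample(0:1, 30, TRUE),
    z_tnbc_l2 = round(rnorm(30), 1) * sample(0:1, 30, TRUE),
    z_final = round(rnorm(30, sd = 2), 2),
    fdr = runif(30)
  )
  expressed <- sample(rnd$ctl_gene, 25)
  got <- suppressMessages(
    shortlist_candidates(rnd, make_calls("CTL", expressed)))
  want <- brute_shortlist(as.data.frame(rnd), expressed)
  expect_setequal(got$ctl_gene, want$ctl_gene)
})

test_that("method relations: |Strict| <= |Composite| <= |Tolerant|-compatible", {
  set.seed(13)
  n <- 200
  oriented <- tibble::tibble(ctl_gene = paste0("L", 1:n),
                             tnbc_gene = paste0("R", 1:n),
                             ctl_role = "ligand",
                             ligand_gene = paste0("L", 1:n),
                             receptor_gene = paste0("R", 1:n))
  ctl <- tibble::tibble(gene_id = oriented$ctl_gene, normZ = rnorm(n))
  tnbc <- make_tnbc_scores(c("l1", "l2"), oriented$tnbc_gene,
                           list(rnorm(n), rnorm(n)))
  z <- purrr::map(c("tolerant", "strict", "composite"), function(m) {
    suppressMessages(
      score_interactions(oriented, ctl, tnbc, m))$z_final
  })
  names(z) <- c("tolerant", "strict", "composite")
  expect_true(all(abs(z$strict) <= abs(z$composite) + 1e-12))
  # when all within-pair signs agree, Composite equals Tolerant
  agree <- purrr::map_lgl(seq_len(n), function(i) {
    s <- sign(c(ctl$normZ[i], tnbc$normZ[c(i, n + i)]))
    s <- s[s != 0]
    length(s) == 0 || all(s == s[1])
  })
  expect_equal(z$composite[agree], z$tolerant[agree])

  # Tolerant z_final is linear: scaling all inputs by c scales output by c
  ctl2 <- dplyr::mutate(ctl, normZ = normZ * 2.5)
  tnbc2 <- dplyr::mutate(tnbc, normZ = normZ * 2.5)
  z2 <- suppressMessages(
    score_interactions(oriented, ctl2, tnbc2, "tolerant"))$z_final
  expect_equal(z2, z$tolerant * 2.5)
})

test_that("tolerant combination of i.i.d. N(0,1) inputs is N(0,1) per line", {
  set.seed(99)
  n <- 10000
  oriented <- tibble::tibble(ctl_gene = paste0("L", 1:n),
                             tnbc_gene = paste0("R", 1:n),
                             ctl_role = "ligand",
                             ligand_gene = paste0("L", 1:n),
                             receptor_gene = paste0("R", 1:n))
  ctl <- tibble::tibble(gene_id = oriented$ctl_gene, normZ = rnorm(n))
  tnbc <- make_tnbc_scores("l1", oriented$tnbc_gene, list(rnorm(n)))
  z <- suppressMessages(
    score_interactions(oriented, ctl, tnbc, "tolerant"))$z_final
  expect_gt(ks.test(z, pnorm)$p.value, 0.01)

  # with two cell lines sharing the CTL score, the final score inflates
  # to variance 1.5 -- the per-line score is the exactly calibrated one
  tnbc2 <- make_tnbc_scores(c("l1", "l2"), oriented$tnbc_gene,
                            list(rnorm(n), rnorm(n)))
  z2 <- suppressMessages(
    score_interactions(oriented, ctl, tnbc2, "tolerant"))$z_final
  expect_lt(abs(stats::var(z2) - 1.5), 0.1)
})

test_that("zeroing one side collapses the final score onto the other", {
  oriented <- tibble::tibble(ctl_gene = "L", tnbc_gene = "R",
                             ctl_role = "ligand",
                             ligand_gene = "L", receptor_gene = "R")
  ctl <- tibble::tibble(gene_id = "L", normZ = -3.28)
  tnbc <- make_tnbc_scores(c("l1", "l2"), "R", list(0, 0))
  z <- suppressMessages(
    score_interactions(oriented, ctl, tnbc, "tolerant"))$z_final
  # ((z+0)/sqrt(2) + (z+0)/sqrt(2)) / sqrt(2) = z
  expect_equal(z, -3.28)
})
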