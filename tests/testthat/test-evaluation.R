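test_that("classification thresholds: sign, significance, strict boundary", {
  tab <- tibble::tibble(
    ctl_gene = paste0("g", 1:4), tnbc_gene = paste0("h", 1:4),
    z_final = c(4.0, -4.0, -4.0, 2.0),
    fdr = c(0.001, 0.20, 0.01, 0.05)
  )
  out <- classify_scores(tab, fdr_threshold = 0.05)
  expect_equal(as.character(out$prediction),
               c("activating", "unknown", "suppressive", "unknown"))
  # row 4: fdr exactly at the threshold stays unknown (strict <)
})

test_that("standard matching is unordered and picks the max-|z| orientation", {
  std <- tibble::tibble(gene_a = c("Pdcd1", "X"), gene_b = c("Cd274", "Y"),
                        label = c("suppressive", "activating"),
                        tier = "gold")
  scored <- tibble::tibble(
    ctl_gene = c("Pdcd1", "Cd274", "other"),
    tnbc_gene = c("Cd274", "Pdcd1", "partner"),
    z_final = c(2, -3, 5),
    fdr = c(0.01, 0.001, 0.001)
  ) |> classify_scores()
  pairs <- match_standard(std, scored)
  # both orientations of Pdcd1-Cd274 collapse to the z = -3 instance
  pd <- pairs[pairs$truth == "suppressive", ]
  expect_equal(nrow(pd), 1)
  expect_equal(pd$z_final, -3)
  # non-standard instance carries truth unknown
  expect_equal(as.character(pairs$truth[pairs$gene_a == "other"]), "unknown")
  # standard pair absent from scores lands in the unmatched report
  unmatched <- attr(pairs, "unmatched")
  expect_equal(unmatched$gene_a, "X")
  # confusion feed size = matched pairs + non-standard instances
  expect_equal(nrow(pairs), 2)
})

test_that("confusion metrics: perfect, degenerate, and macro averaging", {
  perfect <- tibble::tibble(
    truth = c("activating", "suppressive", "unknown"),
    prediction = c("activating", "suppressive", "unknown")
  )
  rep <- confusion_and_metrics(perfect)
  expect_equal(rep$macro_precision, 1)
  expect_equal(rep$macro_recall, 1)
  expect_equal(rep$macro_f1, 1)
  expect_equal(sum(rep$confusion), 3)
  expect_equal(unname(rowSums(rep$confusion)), c(1, 1, 1))

  all_unknown <- tibble::tibble(
    truth = c("activating", "suppressive"),
    prediction = c("unknown", "unknown")
  )
  rep0 <- confusion_and_metrics(all_unknown)
  expect_equal(rep0$macro_recall, 0)
  expect_equal(rep0$macro_f1, 0)

  one_class <- tibble::tibble(truth = c("activating", "unknown"),
                              prediction = c("activating", "unknown"))
  expect_warning(rep1 <- confusion_and_metrics(one_class), "no truth")
  expect_equal(rep1$macro_recall, 1) # averaged over the remaining class
})

test_that("macro F1 is the arithmetic mean of class F1s, not harmonic of P/R", {
  pairs <- dplyr::bind_rows(
    tibble::tibble(truth = "activating",
                   prediction = rep(c("activating", "unknown"), c(30, 49))),
    tibble::tibble(truth = "suppressive",
                   prediction = rep(c("suppressive", "unknown"), c(4, 26))),
    tibble::tibble(truth = "unknown",
                   prediction = rep(c("activating", "suppressive", "unknown"),
                                    c(20, 1, 100)))
  )
  rep <- confusion_and_metrics(pairs)
  f1s <- rep$per_class$f1
  expect_equal(rep$macro_f1, mean(f1s))
  expect_equal(mean(f1s), 0.347, tolerance = 1e-3)
  harmonic <- 2 * rep$macro_precision * rep$macro_recall /
    (rep$macro_precision + rep$macro_recall)
  expect_gt(abs(harmonic - rep$macro_f1), 0.02)
})

test_that("AUROC: separation, ties, oracle equivalence, monotone invariance", {
  expect_equal(auroc(c(2, 3, -1, -2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_true(is.na(auroc(c(1, 2), c(TRUE, TRUE))))

  set.seed(55)
  scores <- round(rnorm(20), 1) # rounding forces some ties
  pos <- runif(20) < 0.4
  expect_equal(auroc(scores, pos), brute_auroc(scores, pos))
  # invariance under a strictly monotone transform
  expect_equal(auroc(exp(scores), pos), auroc(scores, pos))
  expect_equal(auroc(rank(scores), pos), auroc(scores, pos))
})

test_that("tidy and glance expose per-class and macro summaries", {
  pairs <- tibble::tibble(
    truth = c("activating", "activating", "suppressive", "unknown"),
    prediction = c("activating", "unknown", "suppressive", "unknown"),
    z_final = c(3, 1, -3, 0.1)
  )
  rep <- confusion_and_metrics(pairs)
  td <- tidy(rep)
  expect_equal(td$class, c("activating", "suppressive"))
  expect_true(all(c("precision", "recall", "f1") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$auroc, 1) # positives {3,1} all above negatives {-3}
})
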