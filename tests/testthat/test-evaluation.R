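test_that("one-vs-rest confusion counts treat TC/NON as negatives", {
  gold <- structure(list("1" = "PTC"), class = "gold_labels")
  pred <- list("1" = "PTC")
  expect_identical(confusion_counts(pred, gold, "PTC"),
                   c(TP = 1L, FP = 0L, FN = 0L, TN = 0L))
  expect_identical(confusion_counts(pred, gold, "ATC"),
                   c(TP = 0L, FP = 0L, FN = 0L, TN = 1L))

  # multi-label gold evaluated separately per label
  gold2 <- structure(list("1" = c("PTC", "FTC")), class = "gold_labels")
  pred2 <- list("1" = "PTC")
  expect_identical(confusion_counts(pred2, gold2, "PTC")[["TP"]], 1L)
  expect_identical(confusion_counts(pred2, gold2, "FTC")[["FN"]], 1L)

  # TC and NON predictions are negative for every subtype
  predTC <- list("1" = "TC")
  expect_identical(confusion_counts(predTC, gold, "PTC")[["FN"]], 1L)

  # a document absent from predictions counts as a negative prediction
  expect_identical(confusion_counts(list(), gold, "PTC")[["FN"]], 1L)

  empty <- structure(list(), class = "gold_labels")
  expect_identical(sum(confusion_counts(pred, empty, "PTC")), 0L)
  expect_error(confusion_counts(pred, gold, "XYZ"), "unknown subtype")
})

test_that("precision/recall/F1 reproduce the published confusion-count arithmetic", {
  m <- prf(641, 14, 186)
  expect_equal(round(unname(m), 3), c(0.979, 0.775, 0.865))
  m2 <- prf(75, 45, 12)
  expect_equal(round(unname(m2), 3), c(0.625, 0.862, 0.725))
  expect_equal(round(prf(189, 4, 41)[["P"]], 3), 0.979)
  expect_equal(round(prf(114, 6, 27)[["R"]], 3), 0.809)
  expect_identical(unname(prf(0, 0, 0)), c(0, 0, 0))
  expect_error(prf(-1, 0, 0), "non-negative")
})

test_that("micro-averaging pools counts before the ratios", {
  counts <- list(
    PTC = c(TP = 641, FP = 14, FN = 186),
    ATC = c(TP = 114, FP = 6, FN = 27),
    FTC = c(TP = 75, FP = 45, FN = 12),
    MTC = c(TP = 189, FP = 4, FN = 41)
  )
  m <- micro_average(counts)
  expect_equal(round(unname(m), 3), c(0.937, 0.793, 0.859))

  one <- list(PTC = c(TP = 10, FP = 2, FN = 3))
  expect_equal(micro_average(one), prf(10, 2, 3))

  # identical per-class counts leave the pooled ratios unchanged
  twice <- list(A = c(TP = 10, FP = 2, FN = 3), B = c(TP = 10, FP = 2, FN = 3))
  expect_equal(micro_average(twice), prf(10, 2, 3))
  expect_error(micro_average(list()), "at least one")
})

test_that("evaluation reports compose per-subtype rows plus a micro row", {
  gold <- structure(list("1" = "PTC", "2" = "FTC", "3" = c("PTC", "MTC"),
                         "4" = "ATC"), class = "gold_labels")
  perfect <- list("1" = "PTC", "2" = "FTC", "3" = c("PTC", "MTC"), "4" = "ATC")
  rep1 <- evaluate(perfect, gold)
  expect_equal(rep1$F1, rep(1, 5))

  all_non <- list("1" = "NON", "2" = "NON", "3" = "NON", "4" = "NON")
  rep2 <- evaluate(all_non, gold)
  expect_equal(rep2$R, rep(0, 5))

  # micro counts are the component-wise sums of the per-subtype counts
  for (col in c("TP", "TN", "FN", "FP")) {
    expect_equal(rep1[rep1$subtype == "Micro", col],
                 sum(rep1[rep1$subtype != "Micro", col]))
  }
  # counts partition: per subtype TP+FP+FN+TN = number of gold documents
  per <- rep2[rep2$subtype != "Micro", ]
  expect_equal(per$TP + per$FP + per$FN + per$TN, rep(4, 4))
})

test_that("a fixture realizing the published PTC confusion counts reproduces its row", {
  # 641 TP, 14 FP, 186 FN, 372 TN over 1213 documents
  n <- 1213
  pmids <- as.character(seq_len(n))
  gold <- structure(stats::setNames(
    c(rep(list("PTC"), 641 + 186), rep(list("MTC"), 14 + 372)),
    pmids
  ), class = "gold_labels")
  pred <- stats::setNames(
    c(rep(list("PTC"), 641), rep(list("NON"), 186),
      rep(list(c("PTC", "MTC")), 14), rep(list("MTC"), 372)),
    pmids
  )
  rep <- evaluate(pred, gold)
  ptc <- rep[rep$subtype == "PTC", ]
  expect_equal(c(ptc$TP, ptc$FP, ptc$FN, ptc$TN), c(641, 14, 186, 372))
  expect_equal(round(c(ptc$P, ptc$R, ptc$F1), 3), c(0.979, 0.775, 0.865))
})

test_that("F1 lies between precision and recall whenever defined", {
  set.seed(42)
  for (i in 1:50) {
    cc <- sample(0:200, 3, replace = TRUE)
    m <- prf(cc[1], cc[2], cc[3])
    if (m[["P"]] + m[["R"]] > 0) {
      expect_gte(m[["F1"]], min(m[["P"]], m[["R"]]) - 1e-12)
      expect_lte(m[["F1"]], max(m[["P"]], m[["R"]]) + 1e-12)
    }
  }
})

test_that("metrics recomputed from a written report's counts match its printed values", {
  gold <- structure(list("1" = "PTC", "2" = "FTC", "3" = "MTC"),
                    class = "gold_labels")
  pred <- list("1" = "PTC", "2" = "PTC", "3" = "MTC")
  report <- evaluate(pred, gold)
  path <- tempfile(fileext = ".tsv")
  write_evaluation(report, path)
  back <- utils::read.delim(path)
  for (i in seq_len(nrow(back))) {
    m <- prf(back$TP[i], back$FP[i], back$FN[i])
    expect_equal(back$P[i], round(m[["P"]], 3), tolerance = 5e-4)
    expect_equal(back$F1[i], round(m[["F1"]], 3), tolerance = 5e-4)
  }
})

test_that("the DTC reassignment list converts FTC false positives to true positives", {
  gold <- structure(list("1" = "PTC", "2" = "PTC"), class = "gold_labels")
  pred <- list("1" = c("PTC", "FTC"), "2" = "PTC")
  base <- evaluate(pred, gold)
  expect_equal(base[base$subtype == "FTC", "FP"], 1)
  adj <- evaluate(pred, gold, dtc_as_ftc = "1")
  expect_equal(adj[adj$subtype == "FTC", "FP"], 0)
  expect_equal(adj[adj$subtype == "FTC", "TP"], 1)
})
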