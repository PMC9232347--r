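shifted_blocks <- function() {
  A <- matrix(FALSE, 4, 4); A[1:2, 1:2] <- TRUE
  B <- matrix(FALSE, 4, 4); B[1:2, 2:3] <- TRUE
  list(A = A, B = B)
}

test_that("overlap metrics: identity, disjoint and shifted-block cases", {
  m <- shifted_blocks()
  # A = B
  r <- overlap_metrics(m$A, m$A)
  expect_equal(unlist(r[c("AOM", "AVM", "AUM", "CM")]),
               c(AOM = 1, AVM = 0, AUM = 0, CM = 1))
  # disjoint
  C <- matrix(FALSE, 4, 4); C[3:4, 3:4] <- TRUE
  r2 <- overlap_metrics(m$A, C)
  expect_equal(unlist(r2[c("AOM", "AVM", "AUM", "CM")]),
               c(AOM = 0, AVM = 1, AUM = 1, CM = 0))
  # shifted block: |∩|=2, |∪|=6
  r3 <- overlap_metrics(m$A, m$B)
  expect_equal(r3$AOM, 1 / 3)
  expect_equal(r3$AVM, 1 / 2)
  expect_equal(r3$AUM, 1 / 2)
  expect_equal(r3$CM, 4 / 9)
  expect_equal(r3$sen, 1 / 2)
  expect_equal(r3$spe, 1 / 2)
})

test_that("confusion counts match a four-way tally oracle", {
  m <- shifted_blocks()
  expect_equal(confusion_counts(m$A, m$A)[c("FP", "FN")], list(FP = 0L, FN = 0L))
  empty <- matrix(FALSE, 4, 4)
  ce <- confusion_counts(m$A, empty)
  expect_equal(ce$TP, 0L)
  expect_equal(ce$FP, 0L)
  expect_equal(ce$FN, sum(m$A))
  set.seed(401)
  for (i in 1:20) {
    A <- random_mask(); B <- random_mask()
    cc <- confusion_counts(A, B)
    o <- oracle_overlap(A, B)
    expect_equal(cc$TP, o$TP)
    expect_equal(cc$FP, o$FP)
    expect_equal(cc$TN, o$TN)
    expect_equal(cc$FN, o$FN)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, length(A))
  }
  expect_error(confusion_counts(m$A, matrix(FALSE, 2, 2)), "shape")
})

test_that("Sen and Spe follow the printed forms and their mask identities", {
  m <- shifted_blocks()
  cc <- confusion_counts(m$A, m$B)
  ss <- sen_spe(cc)
  expect_equal(unname(ss), c(0.5, 0.5))
  # perfect prediction
  expect_equal(unname(sen_spe(confusion_counts(m$A, m$A))), c(1, 1))
  # cross-identities Sen = 1 - AVM, Spe = 1 - AUM on random pairs
  set.seed(402)
  for (i in 1:30) {
    A <- random_mask(); B <- random_mask()
    if (!any(A) || !any(B)) next
    r <- overlap_metrics(A, B)
    ss <- sen_spe(confusion_counts(A, B))
    expect_equal(ss[["sen"]], 1 - r$AVM, tolerance = 1e-15)
    expect_equal(ss[["spe"]], 1 - r$AUM, tolerance = 1e-15)
  }
  expect_error(sen_spe(list(TP = 0, FP = 0, TN = 10, FN = 2)), "Spe undefined")
  expect_error(sen_spe(list(TP = 0, FP = 2, TN = 10, FN = 0)), "Sen undefined")
})

test_that("degenerate masks follow the documented conventions", {
  m <- shifted_blocks()
  empty <- matrix(FALSE, 4, 4)
  expect_error(overlap_metrics(empty, m$B), "empty")
  expect_warning(r <- overlap_metrics(m$A, empty), "convention")
  expect_equal(unlist(r[c("AOM", "AVM", "AUM", "CM")]),
               c(AOM = 0, AVM = 1, AUM = 1, CM = 0))
})

test_that("metric suite matches the set-arithmetic oracle on 100 seeded pairs", {
  set.seed(403)
  n_done <- 0
  while (n_done < 100) {
    A <- random_mask(16, 16)
    B <- random_mask(16, 16)
    if (!any(A) || !any(B)) next
    n_done <- n_done + 1
    r <- overlap_metrics(A, B)
    o <- oracle_overlap(A, B)
    expect_identical(r$AOM, o$AOM)
    expect_identical(r$AVM, o$AVM)
    expect_identical(r$AUM, o$AUM)
    expect_identical(r$CM, o$CM)
    expect_identical(r$sen, o$sen)
    expect_identical(r$spe, o$spe)
    # AOM symmetric; AVM/AUM swap under exchanging the roles of A and B
    rs <- overlap_metrics(B, A)
    expect_identical(rs$AOM, r$AOM)
    expect_identical(rs$AVM, r$AUM)
    expect_identical(rs$AUM, r$AVM)
  }
})

test_that("ROC curve handles separable, constant and random maps", {
  A <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  # perfectly separating probabilities
  p <- matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2)
  roc <- roc_curve(p, A)
  expect_equal(attr(roc, "auc"), 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  # constant map: chance diagonal
  expect_equal(attr(roc_curve(matrix(0.5, 2, 2), A), "auc"), 0.5)
  # random maps vs the Mann-Whitney pair-counting oracle
  set.seed(404)
  for (i in 1:10) {
    A <- random_mask(8, 8)
    if (!any(A) || all(A)) next
    p <- matrix(round(runif(64), 2), 8, 8) # rounded: exercises ties
    expect_equal(attr(roc_curve(p, A), "auc"), oracle_auc(p, A))
  }
  expect_error(roc_curve(p, matrix(TRUE, 8, 8)), "both classes")
})

test_that("ROC area agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(405)
  A <- random_mask(12, 12)
  p <- matrix(runif(144), 12, 12)
  ref <- as.numeric(pROC::auc(pROC::roc(as.numeric(A), as.numeric(p),
                                        quiet = TRUE, direction = "<")))
  expect_equal(attr(roc_curve(p, A), "auc"), ref, tolerance = 1e-12)
})
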