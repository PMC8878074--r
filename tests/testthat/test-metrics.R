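test_that("dice handles the worked examples and is symmetric", {
  a <- matrix(0, 8, 8); a[2:5, 2:5] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 8, 8); b[6:8, 6:8] <- 1
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 16 with 8 shared pixels: 2*8 / 32 = 0.5
  c2 <- matrix(0, 8, 8); c2[2:5, 4:7] <- 1
  expect_equal(sum(a), 16); expect_equal(sum(c2), 16)
  expect_equal(sum(a & c2), 8)
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(c2, a), dice(a, c2))
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice(a, matrix(0, 4, 4)), "mismatch")
})

test_that("precision/recall/F1 follow their definitions", {
  a <- matrix(0, 8, 8); a[1:4, 1:4] <- 1
  expect_equal(unname(pixel_prf(a, a)), c(1, 1, 1))
  # TP = 8, FP = 8, FN = 8 by construction
  pred <- matrix(0, 8, 8); truth <- matrix(0, 8, 8)
  pred[1:2, 1:8] <- 1   # 16 predicted
  truth[1:1, 1:8] <- 1  # row 1 shared (TP = 8), row 2 FP = 8
  truth[3, 1:8] <- 1    # FN = 8
  cc <- confusion_counts(pred, truth)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(8, 8, 8))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 64)
  expect_equal(unname(pixel_prf(pred, truth)), c(0.5, 0.5, 0.5))
  # random masks against an explicit per-pixel counting oracle
  set.seed(41)
  for (rep in 1:10) {
    p <- matrix(rbinom(256, 1, 0.3), 16, 16)
    t2 <- matrix(rbinom(256, 1, 0.3), 16, 16)
    tp <- 0; fp <- 0; fn <- 0
    for (i in 1:16) for (j in 1:16) {
      if (p[i, j] && t2[i, j]) tp <- tp + 1
      if (p[i, j] && !t2[i, j]) fp <- fp + 1
      if (!p[i, j] && t2[i, j]) fn <- fn + 1
    }
    got <- pixel_prf(p, t2)
    expect_equal(unname(got["precision"]), if (tp + fp == 0) 1 else tp / (tp + fp))
    expect_equal(unname(got["recall"]), if (tp + fn == 0) 1 else tp / (tp + fn))
  }
  # degenerate conventions
  expect_equal(unname(pixel_prf(matrix(0, 2, 2), matrix(0, 2, 2))), c(1, 1, 1))
})

test_that("AJI reproduces the hand-derived worked cases", {
  truth <- matrix(0L, 12, 12)
  truth[3:6, 3:6] <- 1L  # one 4x4 nucleus, 16 px
  expect_equal(aji(truth, truth), 1)
  # same square shifted 2 px: intersection 8, union 24
  pred <- matrix(0L, 12, 12)
  pred[3:6, 5:8] <- 1L
  expect_equal(aji(truth, pred), 8 / 24, tolerance = 1e-12)
  # plus a spurious 4-pixel prediction: rest adds 4 to the denominator
  pred2 <- pred
  pred2[10:11, 10:11] <- 2L
  expect_equal(aji(truth, pred2), 8 / 28, tolerance = 1e-12)
  # adding an unmatched prediction strictly decreases the score
  expect_lt(aji(truth, pred2), aji(truth, pred))
  # asymmetry: three truth nuclei against one prediction that best matches
  # the largest; reversing the roles changes both matching and rest terms
  t2 <- rbind(c(0, 0, 0, 0, 1, 1, 1, 0),
              c(0, 0, 0, 0, 1, 1, 1, 0),
              c(0, 0, 0, 3, 3, 3, 1, 0),
              c(0, 0, 3, 3, 3, 3, 0, 0),
              c(0, 0, 3, 3, 3, 3, 3, 0),
              c(0, 0, 3, 3, 3, 3, 2, 0),
              c(0, 0, 0, 3, 3, 2, 2, 0),
              c(0, 0, 0, 2, 2, 2, 2, 0))
  p2 <- rbind(c(0, 0, 0, 0, 0, 0, 0, 0),
              c(0, 0, 0, 0, 0, 0, 0, 0),
              c(0, 0, 0, 0, 1, 1, 1, 0),
              c(0, 0, 0, 1, 1, 1, 1, 1),
              c(0, 0, 0, 0, 1, 1, 1, 1),
              c(0, 0, 0, 0, 1, 1, 1, 0),
              c(0, 0, 0, 0, 0, 0, 0, 0),
              c(0, 0, 0, 0, 0, 0, 0, 0))
  expect_false(isTRUE(all.equal(aji(t2, p2), aji(p2, t2))))
  expect_equal(aji(t2, p2), oracle_aji(t2, p2), tolerance = 1e-12)
  expect_equal(aji(p2, t2), oracle_aji(p2, t2), tolerance = 1e-12)
})

test_that("AJI equals the brute-force oracle on random label maps", {
  set.seed(42)
  for (rep in 1:200) {
    side <- sample(8:32, 1)
    truth <- random_label_map(side)
    pred <- random_label_map(side)
    expect_equal(aji(truth, pred), oracle_aji(truth, pred), tolerance = 1e-10)
  }
})

test_that("the unmatched-prediction penalty never raises the score", {
  set.seed(43)
  for (rep in 1:25) {
    truth <- random_label_map(24)
    pred <- random_label_map(24)
    # aggregated Jaccard over matched pairs only (no rest term)
    no_rest <- local({
      gl <- sort(setdiff(unique(as.vector(truth)), 0))
      pl <- sort(setdiff(unique(as.vector(pred)), 0))
      used <- rep(FALSE, length(pl)); num <- 0; den <- 0
      for (gi in gl) {
        G <- truth == gi; best <- 0; bj <- 0
        for (j in seq_along(pl)) {
          if (used[j]) next
          inter <- sum(G & (pred == pl[j]))
          if (inter == 0) next
          jac <- inter / sum(G | (pred == pl[j]))
          if (jac > best + 1e-15) { best <- jac; bj <- j }
        }
        if (bj == 0) den <- den + sum(G)
        else { P <- pred == pl[bj]; num <- num + sum(G & P); den <- den + sum(G | P); used[bj] <- TRUE }
      }
      if (den == 0) 1 else num / den
    })
    expect_lte(aji(truth, pred), no_rest + 1e-12)
  }
})

test_that("all metrics stay within [0, 1]", {
  set.seed(44)
  for (rep in 1:20) {
    truth <- random_label_map(16)
    pred <- random_label_map(16)
    r <- metrics_report(truth, pred)
    expect_true(all(r >= 0 & r <= 1))
    expect_named(r, c("dsc", "f1", "recall", "precision", "aji"))
    # F1 is the harmonic mean of precision and recall when both are defined
    if (r["precision"] + r["recall"] > 0) {
      expect_equal(unname(r["f1"]),
                   2 * r[["precision"]] * r[["recall"]] / (r[["precision"]] + r[["recall"]]))
    }
  }
})

test_that("probability maps convert to raster-ordered instance labels", {
  expect_equal(max(instances_from_probability(matrix(0, 10, 10))), 0)
  p <- matrix(0, 12, 12)
  p[2:4, 2:4] <- 0.9
  p[8:11, 7:10] <- 0.8
  lab <- instances_from_probability(p)
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), c(1L, 2L))
  expect_equal(lab[2, 2], 1L)  # first in raster order gets label 1
  expect_equal(lab[9, 8], 2L)
  # sub-minimum components are removed
  p2 <- p; p2[6, 1] <- 0.99
  expect_equal(max(instances_from_probability(p2, min_size = 4)), 2L)
  expect_equal(max(instances_from_probability(p2, min_size = 1)), 3L)
  # component counts agree with an independent flood fill on random blob maps
  set.seed(45)
  for (rep in 1:10) {
    pr <- matrix(0, 24, 24)
    lm <- random_label_map(24)
    pr[lm > 0] <- runif(sum(lm > 0), 0.6, 1)
    lab <- instances_from_probability(pr, min_size = 1)
    expect_equal(max(lab), oracle_count_components(pr > 0.5))
  }
})

test_that("metric tables aggregate by unweighted per-image means", {
  t1 <- matrix(0L, 8, 8); t1[1:3, 1:3] <- 1L
  t2 <- matrix(0L, 8, 8); t2[5:8, 5:8] <- 1L
  p1 <- t1
  p2 <- matrix(0L, 8, 8)
  df <- metrics_table(list(t1, t2), list(p1, p2))
  expect_equal(nrow(df), 3)
  expect_equal(df$image[3], "aggregate")
  expect_equal(df$dsc[3], mean(df$dsc[1:2]))
  expect_equal(df$dsc[1], 1)
  expect_equal(df$dsc[2], 0)
  expect_equal(df$recall[2], 0)
  expect_equal(names(df), c("image", "dsc", "f1", "recall", "precision", "aji"))
})
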