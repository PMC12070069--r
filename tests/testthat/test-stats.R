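test_that("scoring proportions reproduce the printed-percentage convention", {
  tab <- score_phenotypes(data.frame(condition = "Klf2MO", marker = "zic1",
                                     n_scored = 74, n_affected = 67))
  expect_equal(round(tab$percent_affected, 1), 90.5)
  # boundary cases: Wilson interval pinned at the scale ends
  lo <- score_phenotypes(data.frame(condition = "c", marker = "m",
                                    n_scored = 10, n_affected = 0))
  expect_equal(lo$percent_affected, 0)
  expect_equal(lo$ci_low, 0)
  hi <- score_phenotypes(data.frame(condition = "c", marker = "m",
                                    n_scored = 10, n_affected = 10))
  expect_equal(hi$percent_affected, 100)
  expect_equal(hi$ci_high, 100)
})

test_that("Wilson interval endpoints satisfy the score-test defining equation", {
  z <- qnorm(0.975)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    k <- sample(0:n, 1)
    tab <- score_phenotypes(data.frame(condition = "c", marker = "m",
                                       n_scored = n, n_affected = k))
    expect_gte(tab$ci_low, 0); expect_lte(tab$ci_high, 100)
    phat <- k / n
    for (p in c(tab$ci_low, tab$ci_high) / 100) {
      if (p %in% c(0, 1)) next                      # clamped endpoints
      # endpoints solve (phat - p)^2 = z^2 p (1 - p) / n
      expect_equal((phat - p)^2, z^2 * p * (1 - p) / n, tolerance = 1e-9)
    }
  }
})

test_that("scoring validates its invariants", {
  expect_error(score_phenotypes(data.frame(condition = "c", marker = "m",
                                           n_scored = 0, n_affected = 0)),
               "n_scored")
  expect_error(score_phenotypes(data.frame(condition = "c", marker = "m",
                                           n_scored = 5, n_affected = 7)),
               "n_affected")
})

test_that("delta-delta-Ct matches its closed form", {
  # control dCt 5, treated dCt 4 -> ddCt -1, fold 2
  ct <- data.frame(
    sample_group = rep(c("control", "treated"), each = 2),
    replicate = 1,
    gene = rep(c("ODC", "sox3"), 2),
    ct = c(20, 25, 21, 25))
  out <- ddct_fold_change(ct)
  expect_equal(out$ddct, -1)
  expect_equal(out$fold_change, 2)
  # treated identical to control -> fold 1
  ct$ct <- c(20, 25, 20, 25)
  expect_equal(ddct_fold_change(ct)$fold_change, 1)
})

test_that("delta-delta-Ct matches a replicate-by-replicate spreadsheet oracle", {
  set.seed(13)
  genes <- c("sox3", "pou5f3.2", "krt12.4")
  grid <- expand.grid(sample_group = c("control", "treated"), replicate = 1:4,
                      gene = c("ODC", genes), stringsAsFactors = FALSE)
  grid$ct <- round(runif(nrow(grid), 18, 30), 2)
  out <- ddct_fold_change(grid)
  for (g in genes) {
    dct <- function(group) {
      vals <- numeric(0)
      for (r in 1:4) {
        ct_g <- grid$ct[grid$sample_group == group & grid$replicate == r & grid$gene == g]
        ct_ref <- grid$ct[grid$sample_group == group & grid$replicate == r & grid$gene == "ODC"]
        vals <- c(vals, ct_g - ct_ref)
      }
      vals
    }
    ddct <- mean(dct("treated")) - mean(dct("control"))
    row <- out[out$gene == g, ]
    expect_equal(row$ddct, ddct, tolerance = 1e-12)
    expect_equal(row$fold_change, 2^(-ddct), tolerance = 1e-12)
  }
})

test_that("delta-delta-Ct is invariant to per-replicate Ct offsets and names missing references", {
  set.seed(17)
  ct <- expand.grid(sample_group = c("control", "treated"), replicate = 1:3,
                    gene = c("ODC", "sox3"), stringsAsFactors = FALSE)
  ct$ct <- runif(nrow(ct), 20, 28)
  base <- ddct_fold_change(ct)
  shifted <- ct
  for (g in unique(paste(ct$sample_group, ct$replicate))) {
    idx <- paste(ct$sample_group, ct$replicate) == g
    shifted$ct[idx] <- shifted$ct[idx] + runif(1, -3, 3)
  }
  expect_equal(ddct_fold_change(shifted)$fold_change, base$fold_change,
               tolerance = 1e-9)
  broken <- ct[!(ct$gene == "ODC" & ct$replicate == 2 & ct$sample_group == "treated"), ]
  expect_error(ddct_fold_change(broken), "treated 2")
})

test_that("fold-change test handles closed-form and degenerate cases", {
  zero_var <- data.frame(gene = "g", group = rep(c("a", "b"), each = 3),
                         value = c(2, 2, 2, 1, 1, 1))
  expect_warning(out <- fold_change_test(zero_var, "a", "b"), "zero")
  expect_equal(out$fold_change, 2)
  expect_equal(out$p_value, 0)
  expect_true(out$zero_variance)

  same <- data.frame(gene = "g", group = rep(c("a", "b"), each = 3),
                     value = rep(c(1, 2, 3), 2))
  out2 <- fold_change_test(same, "a", "b")
  expect_equal(out2$fold_change, 1)
  expect_equal(out2$t, 0)
  expect_equal(out2$p_value, 1)
})

test_that("fold-change test is symmetric under group swap", {
  set.seed(19)
  df <- data.frame(gene = "klf2", group = rep(c("a", "b"), each = 5),
                   value = c(rnorm(5, 10), rnorm(5, 8)))
  ab <- fold_change_test(df, "a", "b")
  ba <- fold_change_test(df, "b", "a")
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
})

test_that("packaged example tables load and analyse cleanly", {
  sc <- system.file("extdata", "scoring_counts.csv", package = "hcrprofile")
  tab <- score_phenotypes(read_scoring_table(sc))
  expect_equal(nrow(tab), 10L)
  expect_true(all(tab$ci_low <= tab$percent_affected &
                    tab$percent_affected <= tab$ci_high))
  ctf <- system.file("extdata", "synthetic_ct.csv", package = "hcrprofile")
  out <- ddct_fold_change(read_ct_table(ctf))
  expect_setequal(out$gene, c("krt12.4", "pou5f3.2"))
  expect_lt(out$fold_change[out$gene == "krt12.4"], 1)   # depleted marker
  expect_gt(out$fold_change[out$gene == "pou5f3.2"], 1)  # prolonged pluripotency marker
})

test_that("stats tables read from delimited text with header validation", {
  dir <- withr::local_tempdir()
  sc <- file.path(dir, "scoring.csv")
  writeLines("condition,marker,n_scored,n_affected\nKlf2MO,zic1,74,67", sc)
  expect_equal(score_phenotypes(read_scoring_table(sc))$n_affected, 67)
  bad <- file.path(dir, "bad.csv")
  writeLines("condition,n\nx,1", bad)
  expect_error(read_scoring_table(bad), "missing columns")
  ctf <- file.path(dir, "ct.csv")
  writeLines(c("sample_group,replicate,gene,ct",
               "control,1,ODC,20", "control,1,sox3,25",
               "treated,1,ODC,21", "treated,1,sox3,25"), ctf)
  expect_equal(ddct_fold_change(read_ct_table(ctf))$fold_change, 2)
})
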