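two_group_meta <- function(na, nb) {
  data.frame(sample_id = c(paste0("a", seq_len(na)), paste0("b", seq_len(nb))),
             donor_id = c(paste0("da", seq_len(na)), paste0("db", seq_len(nb))),
             condition = rep(c("IBM", "control"), c(na, nb)),
             subtype = "A", replicate_index = 1, stringsAsFactors = FALSE)
}

test_that("t statistics match the closed form and stats::t.test", {
  meta <- two_group_meta(3, 3)
  x <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("P1", meta$sample_id))
  de <- ttest_condition(x, meta, "IBM", "control")
  # pooled sd = 1, se = sqrt(2/3), t = -3 / se
  expect_equal(de$statistic, -3 / sqrt(2 / 3))
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(de$p, ref$p.value)
  expect_equal(de$log2fc, -3)

  # identical groups: t = 0, p = 1 by convention
  eq <- matrix(rep(2, 6), 1, 6, dimnames = list("P1", meta$sample_id))
  deq <- suppressMessages(ttest_condition(eq, meta, "IBM", "control"))
  expect_equal(deq$statistic, 0)
  expect_equal(deq$p, 1)
})

test_that("vectorized t-test agrees with per-protein stats::t.test", {
  set.seed(3)
  meta <- two_group_meta(9, 4)
  x <- matrix(rnorm(50 * 13), 50, 13, dimnames = list(sprintf("P%02d", 1:50),
                                                      meta$sample_id))
  for (variant in c("student", "welch")) {
    de <- ttest_condition(x, meta, "IBM", "control", variant = variant)
    for (i in c(1, 17, 50)) {
      ref <- t.test(x[i, 1:9], x[i, 10:13], var.equal = variant == "student")
      expect_equal(de$p[i], ref$p.value, tolerance = 1e-12)
      expect_equal(de$statistic[i], unname(ref$statistic), tolerance = 1e-12)
    }
    expect_equal(de$q, adjust_by(de$p))
  }
})

test_that("t-test is invariant to column order and row-wise shifts", {
  set.seed(8)
  meta <- two_group_meta(5, 4)
  x <- matrix(rnorm(30 * 9), 30, 9, dimnames = list(sprintf("P%02d", 1:30),
                                                    meta$sample_id))
  de1 <- ttest_condition(x, meta, "IBM", "control")
  perm <- sample(ncol(x))
  de2 <- ttest_condition(x[, perm], meta, "IBM", "control")
  expect_equal(de1$p, de2$p)
  de3 <- ttest_condition(x + 5, meta, "IBM", "control")
  expect_equal(de1$p, de3$p)
})

test_that("two-way ANOVA matches lm/anova per protein", {
  set.seed(4)
  meta <- data.frame(sample_id = paste0("s", 1:9),
                     donor_id = rep(paste0("d", 1:3), each = 3),
                     condition = "IBM",
                     subtype = rep(c("eMyH-F", "CN-F", "Inf-F"), 3),
                     replicate_index = 1, stringsAsFactors = FALSE)
  x <- matrix(rnorm(40 * 9), 40, 9, dimnames = list(sprintf("P%02d", 1:40),
                                                    meta$sample_id))
  x[1, ] <- x[1, ] + ifelse(meta$subtype == "CN-F", 2, 0)
  de <- anova_subtypes(x, meta)
  for (i in c(1, 2, 40)) {
    fit <- lm(x[i, ] ~ factor(meta$donor_id) + factor(meta$subtype))
    a <- anova(fit)
    expect_equal(de$statistic[i], a$`F value`[2], tolerance = 1e-10)
    expect_equal(de$p[i], a$`Pr(>F)`[2], tolerance = 1e-10)
  }
  # one-way variant against aov
  de1 <- anova_subtypes(x, meta, one_way = TRUE)
  a1 <- summary(aov(x[1, ] ~ factor(meta$subtype)))[[1]]
  expect_equal(de1$statistic[1], a1$`F value`[1], tolerance = 1e-10)
  expect_equal(de1$p[1], a1$`Pr(>F)`[1], tolerance = 1e-10)
  # flat protein: F = 0, p = 1
  flat <- matrix(3, 2, 9, dimnames = list(c("P1", "P2"), meta$sample_id))
  def <- anova_subtypes(flat, meta)
  expect_equal(def$statistic, c(0, 0))
  expect_equal(def$p, c(1, 1))
  # shift invariance
  expect_equal(anova_subtypes(x + 7, meta)$p, de$p)
})

test_that("subtype p-values are uniform under the null", {
  set.seed(6)
  pvals <- unlist(lapply(1:3, function(s) {
    sim <- simulate_dataset(sim_config(n_proteins = 400, seed = s,
                                       frac_de = 0, frac_subtype_unique = 0,
                                       missing_intercept = 50,
                                       missing_slope = 0))
    prep <- preprocess_pipeline(sim$table, sim$meta, filters = 1,
                                impute = FALSE, seed = s)
    anova_subtypes(prep$averaged, condition = "IBM")$p
  }))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("uniqueness classes come from the detection mask alone", {
  meta <- two_group_meta(3, 3)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,   # IBM only
                   TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,    # both
                   FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,  # control only
                   FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
                 4, 6, byrow = TRUE,
                 dimnames = list(paste0("P", 1:4), meta$sample_id))
  cls <- classify_uniques(mask, meta)
  expect_equal(unname(cls), c("unique-to-IBM", "shared", "unique-to-control",
                              "none"))
  # brute force on random masks
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(runif(20 * 6) < 0.3, 20, 6,
                dimnames = list(sprintf("P%02d", 1:20), meta$sample_id))
    cls <- classify_uniques(m, meta)
    for (pr in rownames(m)) {
      gA <- any(m[pr, meta$condition == "IBM"])
      gB <- any(m[pr, meta$condition == "control"])
      want <- if (gA && gB) "shared" else if (gA) "unique-to-IBM"
              else if (gB) "unique-to-control" else "none"
      expect_equal(unname(cls[pr]), want)
    }
  }
})

test_that("PCA variance fractions behave as expected", {
  set.seed(12)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("P%02d", 1:20), paste0("s", 1:10)))
  pc <- pca_summary(x)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  # duplicated samples get identical scores
  dup <- cbind(x, x[, 1, drop = FALSE])
  colnames(dup)[11] <- "s1b"
  pcd <- pca_summary(dup)
  expect_equal(unname(pcd$scores["s1", ]), unname(pcd$scores["s1b", ]))
  # two samples: a single direction of variation
  pc2 <- pca_summary(x[, 1:2])
  expect_equal(pc2$var_explained[1], 1, tolerance = 1e-9)
  expect_error(pca_summary(matrix(1, 3, 3,
                                  dimnames = list(paste0("P", 1:3),
                                                  paste0("s", 1:3)))),
               "constant")
})

test_that("protein ratio contrast computes log2 ratios and detects shifts", {
  meta <- two_group_meta(4, 4)
  x <- matrix(3, 2, 8, dimnames = list(c("MYH2", "MYH7"), meta$sample_id))
  rc <- ratio_contrast(x, meta, group_a = "IBM", group_b = "control")
  expect_equal(unname(rc$ratio), rep(0, 8))
  expect_equal(rc$p, 1)
  x["MYH2", 1] <- 5
  x["MYH7", 1] <- 3
  expect_equal(unname(ratio_contrast(x, meta)$ratio[1]), 2)
  # simulated disease shift of -1.5 in the ratio is detected directionally
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    y <- matrix(rnorm(16, 20, 0.3), 2, 8,
                dimnames = list(c("MYH2", "MYH7"), meta$sample_id))
    y["MYH2", meta$condition == "IBM"] <-
      y["MYH2", meta$condition == "IBM"] - 1.5
    r <- ratio_contrast(y, meta, group_a = "IBM", group_b = "control")
    r$means["IBM"] < r$means["control"]
  }, logical(1))
  expect_true(all(hits))
  expect_error(ratio_contrast(x, meta, protein_a = "NOPE"), "not found")
})
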