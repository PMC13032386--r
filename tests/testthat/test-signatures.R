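fake_de <- function(proteins, q) {
  structure(data.frame(protein = proteins, gene = proteins, p = q, q = q,
                       significant = q < 0.05, stringsAsFactors = FALSE),
            class = c("fiber_de", "data.frame"),
            test = "fixture", q_threshold = 0.05)
}

subtype_meta <- function(subtypes = c("eMyH-F", "CN-F", "Inf-F"), donors = 2,
                         reps = 2) {
  g <- expand.grid(replicate_index = seq_len(reps), subtype = subtypes,
                   donor_id = paste0("d", seq_len(donors)),
                   stringsAsFactors = FALSE)
  data.frame(sample_id = paste(g$donor_id, g$subtype, g$replicate_index,
                               sep = "_"),
             donor_id = g$donor_id, condition = "IBM", subtype = g$subtype,
             replicate_index = g$replicate_index, stringsAsFactors = FALSE)
}

test_that("signature patterns reflect detection subsets of significant proteins", {
  meta <- subtype_meta()
  mask <- matrix(FALSE, 3, nrow(meta),
                 dimnames = list(paste0("P", 1:3), meta$sample_id))
  mask["P1", meta$subtype %in% c("eMyH-F", "CN-F")] <- TRUE  # pairwise group
  mask["P2", meta$subtype == "Inf-F"] <- TRUE                # unique group
  mask["P3", ] <- TRUE                                       # all three
  de <- fake_de(paste0("P", 1:3), c(0.001, 0.01, 0.2))
  sp <- signature_patterns(de, mask, meta)
  expect_equal(nrow(sp), 2)      # P3 not significant
  expect_equal(sp$pattern[sp$protein == "P1"], "eMyH-F&CN-F")
  expect_equal(sp$pattern[sp$protein == "P2"], "Inf-F")
  gc <- attr(sp, "group_counts")
  expect_equal(sum(gc), nrow(sp))
  expect_equal(unname(gc[["eMyH-F&CN-F"]]), 1)
  # a significant protein with an empty pattern is dropped with a message
  mask["P1", ] <- FALSE
  expect_message(sp2 <- signature_patterns(de, mask, meta), "no remaining")
  expect_equal(attr(sp2, "dropped"), "P1")
})

test_that("per-subtype totals and exclusive groups match brute-force set algebra", {
  meta <- subtype_meta()
  subtypes <- unique(meta$subtype)
  set.seed(14)
  for (i in 1:10) {
    mask <- matrix(runif(30 * nrow(meta)) < 0.35, 30, nrow(meta),
                   dimnames = list(sprintf("P%02d", 1:30), meta$sample_id))
    q <- runif(30)^2
    de <- fake_de(rownames(mask), q)
    sig <- rownames(mask)[q < 0.05]
    detected_in <- function(pr, s) any(mask[pr, meta$subtype == s])
    want_pat <- vapply(sig, function(pr)
      paste(subtypes[vapply(subtypes, detected_in, logical(1), pr = pr)],
            collapse = "&"), character(1))
    keep <- want_pat != ""
    if (!sum(keep)) next
    sp <- suppressMessages(signature_patterns(de, mask, meta))
    expect_equal(sp$pattern, unname(want_pat[keep]))
    # inclusive totals by direct counting
    tot <- vapply(subtypes, function(s)
      sum(vapply(sig[keep], detected_in, logical(1), s = s)), integer(1))
    expect_equal(attr(sp, "subtype_totals"), tot)
    expect_equal(sum(attr(sp, "group_counts")), sum(keep))
  }
})

test_that("venn regions equal brute-force enumeration", {
  v <- venn_counts(list(A = c(1, 2), B = c(2, 3)))
  expect_equal(v$regions$count[v$regions$region == "A"], 1)
  expect_equal(v$regions$count[v$regions$region == "B"], 1)
  expect_equal(v$regions$count[v$regions$region == "A&B"], 1)
  expect_equal(unname(v$exclusive_pct), c(50, 50))
  # disjoint sets: no intersections
  d <- venn_counts(list(A = 1:3, B = 4:5))
  expect_equal(d$regions$count[d$regions$region == "A&B"], 0)
  set.seed(15)
  for (i in 1:10) {
    sets <- list(A = random_genes(8), B = random_genes(12), C = random_genes(5))
    v <- venn_counts(sets)
    brute <- brute_venn(sets)
    for (r in v$regions$region) {
      expect_equal(v$regions$count[v$regions$region == r],
                   length(brute[[r]]))
      expect_setequal(v$members[[r]], if (is.null(brute[[r]])) character(0)
                                      else brute[[r]])
    }
    # inclusion-exclusion: region counts sum to the universe size
    expect_equal(sum(v$regions$count), length(unique(unlist(sets))))
  }
  expect_error(venn_counts(list(1:2, 2:3)), "named")
  expect_error(venn_counts(list(A = 1, B = 2, C = 3, D = 4, E = 5, F = 6)),
               "2-5")
})

test_that("z-scoring and ordering follow the definition", {
  x <- matrix(c(1, 2, 3, 7, 7, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("P1", "P2"), paste0("s", 1:3)))
  z <- zscore_matrix(x)
  expect_equal(unname(z$z["P1", ]), c(-1, 0, 1) * 1.224744871391589,
               tolerance = 1e-12)
  expect_equal(unname(z$z["P2", ]), c(0, 0, 0))
  expect_equal(z$constant_rows, "P2")
  set.seed(16)
  m <- matrix(rnorm(60, 10, 2), 12, 5,
              dimnames = list(sprintf("P%02d", 1:12), paste0("s", 1:5)))
  zm <- zscore_matrix(m)
  expect_true(all(abs(rowMeans(zm$z)) < 1e-9))
  pop_sd <- sqrt(rowMeans((zm$z - rowMeans(zm$z))^2))
  expect_true(all(abs(pop_sd - 1) < 1e-9))
  expect_setequal(zm$row_order, 1:12)
})
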