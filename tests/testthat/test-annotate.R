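test_that("gene-set union normalizes, deduplicates and keeps provenance", {
  g1 <- gene_set(c("A", "B"), "s1")
  g2 <- gene_set(c("B", "C"), "s2")
  g3 <- gene_set(c("C", "D"), "s3")
  u <- union_gene_list(g1, g2, g3)
  expect_setequal(u$members, c("A", "B", "C", "D"))
  expect_equal(length(u), 4)
  expect_equal(unname(u$source["B"]), "s1;s2")
  # identity on a single list; order invariance; idempotence
  expect_setequal(union_gene_list(g1)$members, g1$members)
  expect_setequal(union_gene_list(g3, g1, g2)$members, u$members)
  expect_setequal(union_gene_list(u)$members, u$members)
  # case/whitespace variants collapse
  v <- gene_set(c("Hnrnpa1 ", "HNRNPA1", " hnRNPA1"), "dup")
  expect_equal(v$members, "HNRNPA1")
  expect_error(gene_set(c("", NA), "empty"), "empty")
})

test_that("gene list and GMT readers parse the supported dialects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "vim", "MYH2\tsourceX", " Hspb1 "), f)
  gs <- read_gene_list(f, name = "test")
  expect_setequal(gs$members, c("VIM", "MYH2", "HSPB1"))
  g <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("proteasome\tGO:0000502\tPSMB5\tPSMB8\tPSMA1",
               "lysosome\tGO:0005764\tLAMP1\tCTSD"), g)
  sets <- read_gmt(g)
  expect_equal(names(sets), c("proteasome", "lysosome"))
  expect_setequal(sets$proteasome$members, c("PSMB5", "PSMB8", "PSMA1"))
})

test_that("signature annotation intersects by symbol and summarizes patterns", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     donor_id = rep(c("d1", "d2"), 3),
                     condition = "IBM",
                     subtype = rep(c("eMyH-F", "CN-F", "Inf-F"), each = 2),
                     replicate_index = rep(1:2, 3), stringsAsFactors = FALSE)
  mask <- matrix(FALSE, 4, 6, dimnames = list(paste0("G", 1:4), meta$sample_id))
  mask["G1", meta$subtype == "Inf-F"] <- TRUE
  mask["G2", meta$subtype %in% c("eMyH-F", "CN-F")] <- TRUE
  mask["G3", meta$subtype == "Inf-F"] <- TRUE
  mask["G4", ] <- TRUE
  de <- structure(data.frame(protein = rownames(mask), gene = rownames(mask),
                             q = c(0.01, 0.01, 0.01, 0.01),
                             significant = TRUE, stringsAsFactors = FALSE),
                  class = c("fiber_de", "data.frame"), test = "fixture",
                  q_threshold = 0.05)
  sp <- signature_patterns(de, mask, meta)
  ann <- annotate_signatures(sp, gene_set(c("G1", "G2", "G3"), "agg"))
  expect_equal(nrow(ann$table), 3)
  s <- ann$subtype_summary
  # Inf-F holds G1 and G3, both unique to it
  expect_equal(s$n_unique[s$subtype == "Inf-F"], 2)
  expect_equal(s$pct_unique[s$subtype == "Inf-F"], 100)
  # eMyH-F holds only the shared G2: no unique members
  expect_equal(s$n_unique[s$subtype == "eMyH-F"], 0)
  # disjoint set: zero counts
  none <- annotate_signatures(sp, gene_set("ZZZ", "none")) |>
    suppressMessages()
  expect_equal(nrow(none$table), 0)
  expect_equal(sum(none$pattern_counts), 0)
  # set equal to the signature genes reproduces the pattern proportions
  all_ann <- annotate_signatures(sp, gene_set(sp$gene, "all"))
  expect_equal(as.vector(all_ann$pattern_counts),
               as.vector(attr(sp, "group_counts")))
  # brute-force intersection on random fixtures
  set.seed(17)
  for (i in 1:5) {
    pick <- gene_set(sample(rownames(mask), 2), "rnd")
    a <- suppressMessages(annotate_signatures(sp, pick))
    expect_setequal(a$table$gene, intersect(toupper(sp$gene), pick$members))
  }
})

test_that("category contrasts use BH within the set and flag absent members", {
  meta <- data.frame(sample_id = paste0("s", 1:9),
                     donor_id = rep(paste0("d", 1:3), each = 3),
                     condition = "IBM",
                     subtype = rep(c("eMyH-F", "CN-F", "Inf-F"), 3),
                     replicate_index = 1, stringsAsFactors = FALSE)
  set.seed(18)
  x <- matrix(rnorm(5 * 9), 5, 9,
              dimnames = list(c("PSMB5", "PSMB8", "PSMA1", "MYH2", "ACTB"),
                              meta$sample_id))
  x["PSMB8", meta$subtype == "eMyH-F"] <- x["PSMB8", meta$subtype == "eMyH-F"] + 6
  set <- gene_set(c("PSMB5", "PSMB8", "PSMA1", "LAMP1"), "proteasome")
  cc <- category_contrasts(x, meta, set)
  expect_equal(cc$q[!is.na(cc$p)], adjust_bh(cc$p[!is.na(cc$p)]))
  expect_true(cc$significant[cc$gene == "PSMB8"])
  expect_equal(cc$pattern[cc$gene == "LAMP1"], "not detected")
  expect_error(category_contrasts(x, meta, gene_set(c("LAMP1", "CTSD"), "lys")),
               "fewer than 2")
  # flat values: nothing significant
  flat <- matrix(1, 2, 9, dimnames = list(c("PSMB5", "PSMA1"), meta$sample_id))
  cf <- category_contrasts(flat, meta, set)
  expect_false(any(cf$significant[!is.na(cf$p)]))
})

test_that("study lists validate input and apply the fold-change cutoff", {
  s <- study_de_list(c("VIM", "MYH2", "weak"), c("up", "down", "up"),
                     fold_change = c(2.1, 0.4, 1.2), name = "x")
  expect_equal(s$up, "VIM")      # 1.2-fold entry dropped at load
  expect_equal(s$down, "MYH2")   # 0.4 read as 2.5-fold down
  expect_error(study_de_list(c("VIM", "vim"), "up", name = "dup"),
               "duplicate")
  expect_error(study_de_list(c("VIM", "VIM"), c("up", "down"), name = "conf"),
               "conflicting")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tdirection\tfold_change",
               "VIM\tup\t2.0", "TNNT1\tdown\t3.0"), f)
  r <- read_study_list(f)
  expect_equal(r$up, "VIM")
  expect_equal(r$down, "TNNT1")
})

test_that("cross-study overlap is direction-aware and matches set algebra", {
  s1 <- study_de_list(c("VIM", "X", "D1"), c("up", "up", "down"), name = "ours")
  s2 <- study_de_list(c("VIM", "Y"), c("up", "up"), name = "theirs")
  s3 <- study_de_list(c("D1", "D2"), "down", name = "older")
  ov <- cross_study_overlap(list(s1, s2, s3))
  up <- ov$up   # only s1 and s2 report up-lists
  expect_setequal(up$members[["ours&theirs"]], "VIM")
  expect_equal(up$regions$count[up$regions$region == "ours"], 1)
  down <- ov$down
  expect_setequal(down$members[["ours&older"]], "D1")
  # identical studies overlap fully
  twin <- study_de_list(c("VIM", "X"), "up", name = "twin")
  full <- cross_study_overlap(list(s1, twin))$up
  expect_equal(full$regions$count[full$regions$region == "ours&twin"], 2)
  expect_equal(full$regions$count[full$regions$region == "twin"], 0)
  # combined mode pools directions
  all3 <- cross_study_overlap(list(s1, s2, s3), direction_aware = FALSE)$all
  expect_equal(sum(all3$regions$count), length(unique(c("VIM", "X", "D1",
                                                        "Y", "D2"))))
  # random lists against brute-force enumeration
  set.seed(19)
  for (i in 1:5) {
    a <- study_de_list(random_genes(10), "up", name = "a")
    b <- study_de_list(random_genes(8), "up", name = "b")
    v <- cross_study_overlap(list(a, b))$up
    brute <- brute_venn(list(a = a$up, b = b$up))
    for (r in v$regions$region)
      expect_equal(v$regions$count[v$regions$region == r],
                   length(brute[[r]]))
  }
})
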