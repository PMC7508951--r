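# Global alignment, percent identity and pan-genome categorization.

test_that("global alignment reproduces known optima and tie-breaks", {
  a <- global_align("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$aligned_a, "ACGT")
  expect_equal(identity_pct(a), 100)

  # 3 matches + 1 mismatch beats gapping under gap -1
  a <- global_align("AAAA", "AAAT")
  expect_equal(a$score, 1)
  expect_equal(identity_pct(a), 75)

  # single-letter mismatch ties the two-gap alignment at -2; the
  # deterministic tie-break prefers the substitution column
  a <- global_align("A", "G")
  expect_equal(a$score, -2)
  expect_equal(a$aligned_a, "A")
  expect_equal(a$aligned_b, "G")

  expect_error(global_align("", "ACGT"), class = "conjseq_bad_input")

  # fully disjoint alphabets of equal length: optimum may mix mismatches and
  # gaps, but no column is ever identical
  a <- global_align("AAAA", "TTTT")
  expect_equal(identity_pct(a), 0)
})

test_that("alignment scores match exhaustive matching enumeration", {
  cases <- withr::with_seed(5, {
    lapply(1:40, function(i) {
      list(a = paste(sample(c("A", "C", "G", "T"), sample(1:6, 1),
                            replace = TRUE), collapse = ""),
           b = paste(sample(c("A", "C", "G", "T"), sample(1:6, 1),
                            replace = TRUE), collapse = ""),
           gap = sample(c(-0.5, -1, -2.5), 1))
    })
  })
  for (cs in cases) {
    sc <- align_scoring(match = 1, mismatch = -2, gap = cs$gap)
    expect_equal(global_align(cs$a, cs$b, sc)$score,
                 bf_align_score(cs$a, cs$b, 1, -2, cs$gap),
                 info = paste(cs$a, cs$b, cs$gap))
  }
})

test_that("alignment scores agree with an established aligner on long pairs", {
  pairs <- withr::with_seed(6, lapply(1:10, function(i) {
    list(a = paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                   collapse = ""),
         b = paste(sample(c("A", "C", "G", "T"), 35, replace = TRUE),
                   collapse = ""))
  }))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (pr in pairs) {
    ref <- Biostrings::pairwiseAlignment(pr$a, pr$b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(global_align(pr$a, pr$b)$score, ref)
  }
})

test_that("identity is symmetric and the score-based variant is bounded", {
  pairs <- withr::with_seed(7, lapply(1:20, function(i) {
    list(a = paste(sample(c("A", "C", "G", "T"), sample(5:30, 1),
                          replace = TRUE), collapse = ""),
         b = paste(sample(c("A", "C", "G", "T"), sample(5:30, 1),
                          replace = TRUE), collapse = ""))
  }))
  for (pr in pairs) {
    i_ab <- identity_pct(global_align(pr$a, pr$b))
    i_ba <- identity_pct(global_align(pr$b, pr$a))
    expect_equal(i_ab, i_ba)
    s <- identity_pct(global_align(pr$a, pr$b), method = "score")
    expect_gte(s, 0)
    expect_lte(s, 100)
  }
})

test_that("presence and categories follow the core/soft-core/accessory rules", {
  parent <- gen_plasmid(8, gene_len_range = c(300, 600), seed = 81)
  identical_family <- gen_plasmid_family(parent, 7, sub_rate = 0,
                                         indel_rate = 0, loss_rate = 0,
                                         seed = 1)
  pm <- presence_matrix(parent, identical_family, cutoff = 100)
  expect_true(all(pm$present))
  cats <- categorize_genes(pm)
  expect_true(all(cats$category == "core"))

  # one substitution breaks presence at the 100% cutoff
  mutant <- identical_family[[1]]
  s <- mutant$genes$start[1]
  base <- substr(mutant$sequence, s, s)
  substr(mutant$sequence, s, s) <- setdiff(c("A", "C", "G", "T"), base)[1]
  pm100 <- presence_matrix(parent, list(mutant), cutoff = 100)
  expect_false(pm100$present[pm100$gene_id == mutant$genes$gene_id[1]])

  expect_error(presence_matrix(parent, list()), class = "conjseq_bad_input")
  expect_error(presence_matrix(parent, identical_family, cutoff = 0),
               class = "conjseq_bad_input")
})

test_that("category boundaries: >50% is soft-core, exactly 50% is accessory", {
  fake <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3", "g4"), each = 7),
    target = rep(paste0("t", 1:7), times = 4),
    best_hit = NA_character_, identity = 100, aligned_length = 10L,
    present = c(rep(TRUE, 7),                     # 7/7 core
                rep(c(TRUE, FALSE), c(4, 3)),     # 4/7 soft-core
                rep(c(TRUE, FALSE), c(3, 4)),     # 3/7 accessory
                rep(c(TRUE, FALSE), c(0, 7)))     # 0/7 accessory
  )
  attr(fake, "n_targets") <- 7L
  class(fake) <- c("presence_matrix", class(fake))
  cats <- categorize_genes(fake)
  expect_equal(cats$category[match(c("g1", "g2", "g3", "g4"), cats$gene_id)],
               c("core", "soft_core", "accessory", "accessory"))

  # exactly half: accessory by the strict >50% soft-core rule
  half <- dplyr::filter(fake, target %in% paste0("t", 1:6)) %>%
    dplyr::mutate(present = rep(c(rep(TRUE, 3), rep(FALSE, 3)), 4))
  attr(half, "n_targets") <- 6L
  class(half) <- c("presence_matrix", class(half))
  expect_true(all(categorize_genes(half)$category == "accessory"))
})

test_that("pan-genome partition is complete and monotone in the cutoff", {
  parent <- gen_plasmid(9, gene_len_range = c(300, 600), seed = 91)
  fam <- gen_plasmid_family(parent, 7, sub_rate = 0.05, indel_rate = 0.005,
                            loss_rate = 0.25, seed = 3)
  pms <- presence_at_cutoffs(parent, fam, cutoffs = c(100, 70, 50))
  sizes <- vapply(pms, function(pm) {
    cats <- categorize_genes(pm)
    expect_equal(sort(unique(c(cats$category, "core", "soft_core",
                               "accessory"))),
                 c("accessory", "core", "soft_core"))
    expect_equal(nrow(cats), nrow(parent$genes))  # partition covers all genes
    sum(cats$category == "core")
  }, integer(1))
  # presence at a high cutoff implies presence at any lower cutoff
  expect_true(all(pms$cutoff_100$present <= pms$cutoff_70$present))
  expect_true(all(pms$cutoff_70$present <= pms$cutoff_50$present))
  expect_true(sizes[["cutoff_100"]] <= sizes[["cutoff_70"]])
  expect_true(sizes[["cutoff_70"]] <= sizes[["cutoff_50"]])

  # truth-driven: retained genes are present at 70%, lost genes absent
  pm70 <- pms$cutoff_70
  for (k in seq_along(fam)) {
    kept <- fam[[k]]$truth$retained_genes
    sub <- dplyr::filter(pm70, target == fam[[k]]$id)
    expect_true(all(sub$present[sub$gene_id %in% kept]))
    expect_true(all(!sub$present[!sub$gene_id %in% kept]))
  }
})

test_that("essentiality overlap cross-tabulates categories with calls", {
  cats <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                         category = c("core", "core", "accessory",
                                      "soft_core"))
  ess <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        call = c("essential", "essential", "non_essential",
                                 "no_data"),
                        condition = "insitu")
  tab <- essentiality_overlap(cats, ess)
  expect_equal(sum(tab$n), 4L)
  expect_equal(tab$n[tab$category == "core" & tab$call == "essential"], 2L)
  expect_equal(nrow(tab), 9L)  # zero-filled 3 x 3 grid

  other <- dplyr::mutate(ess, gene_id = paste0("x", gene_id))
  expect_error(essentiality_overlap(cats, other),
               class = "conjseq_gene_mismatch")

  none <- dplyr::mutate(ess, call = "non_essential")
  tab <- essentiality_overlap(cats, none)
  expect_equal(sum(tab$n[tab$call == "essential"]), 0L)
})
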