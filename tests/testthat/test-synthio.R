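# Synthetic-data generators: determinism, ground-truth structure, and the
# statistical properties the downstream analyses rely on.

test_that("gen_plasmid builds a valid annotated plasmid with truth labels", {
  expect_error(gen_plasmid(0), class = "conjseq_sizing_error")
  expect_error(gen_plasmid(2), class = "conjseq_sizing_error")

  p1 <- gen_plasmid(10, seed = 1)
  p2 <- gen_plasmid(10, seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, gen_plasmid(10, seed = 2)))

  p <- gen_plasmid(92, gene_len_range = c(300, 1500), seed = 7)
  g <- p$genes
  expect_equal(nrow(g), 92)
  expect_equal(p$length, nchar(p$sequence))
  expect_false(anyDuplicated(g$gene_id) > 0)
  # non-overlapping, spacers >= 10 bp
  ord <- order(g$start)
  expect_true(all(g$start[ord][-1] - g$end[ord][-92] >= 11))
  expect_true(all(g$end - g$start + 1 >= 300 & g$end - g$start + 1 <= 1500))
  # every essentiality class represented and ids resolvable
  tr <- p$truth
  expect_gte(length(tr$maintenance_essential), 1)
  expect_gte(length(tr$invitro_essential), 1)
  expect_gte(length(tr$insitu_essential), 1)
  expect_true(all(unlist(tr[1:3]) %in% g$gene_id))
})

test_that("insertion libraries are deterministic, dense and condition-aware", {
  p <- gen_plasmid(10, gene_len_range = c(500, 1200), seed = 3)
  cfg <- sim_config(seed = 11, n_insertions = 2000, mean_depth = 50)

  t1 <- gen_insertion_library(p, condition = "initial", cfg = cfg)
  t2 <- gen_insertion_library(p, condition = "initial", cfg = cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$pos >= 1 & t1$pos <= p$length))
  expect_identical(t1$total_mapped[1], sum(t1$count))

  # density: ~2000 requested sites on a ~9 kb plasmid is one per ~5 bp;
  # only sites in maintenance genes (~20% of sequence) are depleted
  expect_gt(nrow(t1), 1400)
  mean_spacing <- p$length / 2000
  expect_lt(mean_spacing, 6)

  expect_error(gen_insertion_library(p, condition = "inplanta", cfg = cfg))
})

test_that("absolute depletion empties essential loci", {
  p <- gen_plasmid(8, seed = 5, depletion_factor = Inf)
  cfg <- sim_config(seed = 2, n_insertions = 1500)
  lib <- gen_insertion_library(p, condition = "initial", cfg = cfg)
  g <- p$genes
  maint <- g[g$gene_id %in% p$truth$maintenance_essential, ]
  inside_maint <- rep(FALSE, nrow(lib))
  for (i in seq_len(nrow(maint))) {
    inside_maint <- inside_maint |
      (lib$pos >= maint$start[i] & lib$pos <= maint$end[i])
  }
  expect_identical(sum(inside_maint), 0L)
})

test_that("depletion ratio statistic matches its expectation over many genes", {
  # Essential loci must stay a minority of the replicon (as in the study),
  # otherwise depth normalization itself shifts the ratio. 10 essential
  # genes out of 200 per replicate pair, >= 200 essential-gene ratios pooled
  # over pairs; empirical mean within 3 SE of 1/d - 1.
  d <- 20
  p <- gen_plasmid(200, gene_len_range = c(150, 250), seed = 13,
                   depletion_factor = d, spacer_range = c(10, 30),
                   class_fractions = c(maintenance = 0.005, invitro = 0.05,
                                       insitu = 0.005))
  ratios <- purrr::map_dfr(1:20, function(rep) {
    cfg <- sim_config(seed = 1000 + rep, n_insertions = 9000, mean_depth = 50)
    sites <- dplyr::bind_rows(
      gen_insertion_library(p, condition = "initial", cfg = cfg,
                            sample_id = "initial_rep1"),
      gen_insertion_library(p, condition = "invitro", cfg = cfg,
                            sample_id = "invitro_rep1")
    ) %>% normalize_depth()
    counts <- gene_read_counts(sites, p)
    essentiality_ratio(
      dplyr::filter(counts, sample_id == "invitro_rep1"),
      dplyr::filter(counts, sample_id == "initial_rep1")
    )
  })
  ess <- dplyr::filter(ratios, gene_id %in% p$truth$invitro_essential,
                       !is.na(ratio))
  expect_gte(nrow(ess), 200)
  se <- stats::sd(ess$ratio) / sqrt(nrow(ess))
  expect_lt(abs(mean(ess$ratio) - (1 / d - 1)), 3 * se)
})

test_that("bottleneck subsampling conserves the total cell count", {
  withr::with_seed(4, {
    out <- bottleneck_subsample(1:500, 10000)
    expect_identical(sum(out$cells), 10000L)
    expect_true(all(out$pos %in% 1:500))
    small <- bottleneck_subsample(1:500, 50)
    expect_identical(sum(small$cells), 50L)
    expect_lte(nrow(small), 50)
  })
})

test_that("CFU assays honour rate limits and are reproducible", {
  expect_error(gen_cfu_assay(n_mice = 0), class = "conjseq_bad_input")
  expect_error(gen_cfu_assay(true_rate = 1.5), class = "conjseq_bad_input")

  cfg <- sim_config(seed = 21)
  a1 <- gen_cfu_assay(true_rate = 1e-4, n_mice = 4, cfg = cfg)
  a2 <- gen_cfu_assay(true_rate = 1e-4, n_mice = 4, cfg = cfg)
  expect_identical(a1, a2)

  zero <- gen_cfu_assay(true_rate = 0, n_mice = 3, cfg = cfg)
  tc <- dplyr::filter(zero, selection == "transconjugant")
  expect_true(all(tc$colonies == 0))

  sat <- gen_cfu_assay(true_rate = 1, n_mice = 4, cfg = cfg)
  rates <- transfer_rates(sat)
  expect_true(all(!rates$censored))
  # saturation: transconjugant counts track recipient counts within
  # Poisson/counting error on the log scale (countable spots hold a few
  # dozen colonies, so each CFU estimate carries ~25-45% noise)
  expect_true(all(abs(log10(rates$value)) < 0.5))
})

test_that("plasmid families mirror their mutation parameters", {
  parent <- gen_plasmid(10, gene_len_range = c(300, 600), seed = 31)

  clones <- gen_plasmid_family(parent, 3, sub_rate = 0, indel_rate = 0,
                               loss_rate = 0, seed = 1)
  expect_true(all(vapply(clones, function(ch) {
    identical(ch$sequence, parent$sequence) &&
      identical(ch$genes$gene_id, parent$genes$gene_id)
  }, logical(1))))

  orphans <- gen_plasmid_family(parent, 2, loss_rate = 1, seed = 1)
  expect_true(all(vapply(orphans, function(ch) nrow(ch$genes) == 0,
                         logical(1))))

  expect_error(gen_plasmid_family(parent, 2, sub_rate = 1),
               class = "conjseq_bad_rate")

  # Monte-Carlo: mean identity of retained genes tracks 1 - sub_rate
  fam <- gen_plasmid_family(parent, 6, sub_rate = 0.05, indel_rate = 0,
                            loss_rate = 0, seed = 5)
  pm <- presence_matrix(parent, fam, cutoff = 50)
  idents <- pm$identity
  expect_gt(length(idents), 50)
  # per-base substitution only changes ~3/4 of hit bases (a substitution can
  # re-draw the same base never, but alignment identity is per column)
  se <- stats::sd(idents) / sqrt(length(idents))
  expect_lt(abs(mean(idents) - 95), max(3 * se, 0.5))
})

test_that("read/alignment emission validates inputs and is deterministic", {
  p <- gen_plasmid(5, gene_len_range = c(300, 500), seed = 41)
  cfg <- sim_config(seed = 6, n_insertions = 300, mean_depth = 10)
  lib <- gen_insertion_library(p, condition = "initial", cfg = cfg)
  expect_error(gen_reads(lib, p, read_len = 20), class = "conjseq_bad_input")
  expect_error(gen_reads(lib, p, read_len = p$length + 1),
               class = "conjseq_bad_input")
  r1 <- gen_reads(lib, p, seed = 8)
  r2 <- gen_reads(lib, p, seed = 8)
  expect_identical(r1$alignments, r2$alignments)
  expect_identical(readLines(r1$sam)[-(1:2)], readLines(r2$sam)[-(1:2)])
})
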