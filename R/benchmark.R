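# Ground-truth recovery benchmark for the essentiality pipeline.

f1_score <- function(predicted, truth, universe) {
  predicted <- intersect(predicted, universe)
  truth <- intersect(truth, universe)
  tp <- length(intersect(predicted, truth))
  c(tp = tp, fp = length(setdiff(predicted, truth)),
    fn = length(setdiff(truth, predicted)))
}

#' Benchmark essentiality recovery on synthetic libraries
#'
#' Simulates complete insertion experiments with known ground truth and
#' measures how well the pipeline recovers the essential gene sets. Per seed:
#' a plasmid is generated, libraries for all conditions and replicates are
#' simulated, counts are normalized and the transfer conditions analysed
#' with the true core sets as calibration. Genes flagged by the
#' [maintenance_screen()] (too few insertion sites in the initial library to
#' be scoreable — by construction the maintenance-essential loci) are
#' excluded from the transfer-condition evaluation universe, exactly as
#' unscoreable low-coverage loci are set aside before ratio analysis; `no_data`
#' genes are likewise not counted against either set. The expected essential
#' set is cumulative in selection history: the in vitro set for `invitro`,
#' in vitro plus in situ (mating-pair stabilisation) genes for `insitu`.
#'
#' Counts are pooled over seeds (micro-averaged F1).
#'
#' @param seeds Integer vector of simulation seeds.
#' @param n_genes Genes per synthetic plasmid.
#' @param cfg_template A [sim_config()]; its seed is replaced per run.
#' @param n_reps Replicates per condition.
#' @param depletion_factor Fold depletion of essential-gene insertions.
#' @param gene_len_range Gene length range (bp).
#'
#' @return Tibble per condition (`invitro`, `insitu`, `maintenance`):
#'   pooled `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
benchmark_essentiality <- function(seeds = 1:20, n_genes = 10,
                                   cfg_template = sim_config(
                                     n_insertions = 2000, mean_depth = 50),
                                   n_reps = 3,
                                   depletion_factor = 1000,
                                   gene_len_range = c(500, 1200)) {
  tallies <- purrr::map_dfr(seeds, function(s) {
    plasmid <- gen_plasmid(n_genes, gene_len_range = gene_len_range, seed = s,
                           depletion_factor = depletion_factor)
    cfg <- sim_config(seed = s,
                      n_insertions = cfg_template$n_insertions,
                      mean_depth = cfg_template$mean_depth,
                      bottleneck_size = cfg_template$bottleneck_size,
                      mouse_cv = cfg_template$mouse_cv)
    sites <- gen_hdtm_experiment(plasmid, n_reps = n_reps, cfg = cfg) %>%
      normalize_depth()
    counts <- gene_read_counts(sites, plasmid)
    maint <- maintenance_screen(
      dplyr::filter(sites, .data$condition == "initial"), plasmid
    )
    screened_out <- maint$gene_id[maint$call == "essential"]
    truth <- plasmid$truth
    maint_f1 <- f1_score(screened_out, truth$maintenance_essential,
                         plasmid$genes$gene_id)
    per_cond <- purrr::map_dfr(c("invitro", "insitu"), function(cond) {
      core <- if (cond == "invitro") truth$invitro_essential else
        truth$insitu_essential
      res <- essentiality(counts, cond, core = core)
      tab <- res$table
      universe <- setdiff(tab$gene_id[tab$call != "no_data"], screened_out)
      expected <- if (cond == "invitro") truth$invitro_essential else
        union(truth$invitro_essential, truth$insitu_essential)
      cts <- f1_score(tab$gene_id[tab$call == "essential"], expected, universe)
      tibble(condition = cond, tp = cts[["tp"]], fp = cts[["fp"]],
             fn = cts[["fn"]])
    })
    dplyr::bind_rows(
      per_cond,
      tibble(condition = "maintenance", tp = maint_f1[["tp"]],
             fp = maint_f1[["fp"]], fn = maint_f1[["fn"]])
    )
  })
  tallies %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(dplyr::across(c("tp", "fp", "fn"), sum),
                     .groups = "drop") %>%
    dplyr::mutate(
      precision = .data$tp / (.data$tp + .data$fp),
      recall = .data$tp / (.data$tp + .data$fn),
      f1 = 2 * .data$precision * .data$recall /
        (.data$precision + .data$recall)
    )
}
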