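# Per-gene read counting, depletion ratios and core-set-calibrated
# essentiality calls.

# 1-based offset of positions from the 5' end of a gene on its coding strand,
# NA for positions outside the gene. Handles wrap-around genes (end < start)
# on circular plasmids by unwrapping onto a doubled coordinate view.
gene_offset <- function(pos, start, end, strand, plasmid_len) {
  if (end >= start) {
    inside <- pos >= start & pos <= end
    fwd_off <- pos - start + 1L
    rev_off <- end - pos + 1L
  } else {
    inside <- pos >= start | pos <= end
    unwrapped <- ifelse(pos >= start, pos, pos + plasmid_len)
    end2 <- end + plasmid_len
    fwd_off <- unwrapped - start + 1L
    rev_off <- end2 - unwrapped + 1L
  }
  off <- if (strand == "-") rev_off else fwd_off
  ifelse(inside, off, NA_integer_)
}

#' Per-gene insertion read counts with end trimming
#'
#' Sums normalized (and raw) insertion-site counts per gene, excluding sites
#' in the first `head_trim` and last `tail_trim` fraction of each gene:
#' insertions there can leave functional gene fragments and would blur the
#' essentiality signal. "First" is the 5' end of the coding strand, so the
#' window is strand-aware. A site at 1-based offset `o` from the 5' end of a
#' gene of length `L` is counted when `floor(head_trim*L) < o <=
#' ceiling((1-tail_trim)*L)`.
#'
#' @param sites Normalized insertion-site tibble (any number of samples; run
#'   [normalize_depth()] first).
#' @param plasmid An `annotated_plasmid` supplying the gene annotation.
#' @param head_trim,tail_trim Fractions of the gene length trimmed at the 5'
#'   and 3' ends (defaults 5% and 15%).
#'
#' @return Tibble with one row per gene x sample: `gene_id`, `sample_id`,
#'   `condition`, `raw_count`, `norm_count` (genes without sites get zeros).
#' @export
gene_read_counts <- function(sites, plasmid, head_trim = 0.05,
                             tail_trim = 0.15) {
  stopifnot(inherits(plasmid, "annotated_plasmid"))
  if (!"norm_count" %in% names(sites)) {
    abort_conjseq("sites table lacks norm_count; run normalize_depth() first",
                  "conjseq_bad_input")
  }
  g <- plasmid$genes
  bad <- g$start > plasmid$length | g$end > plasmid$length
  if (any(bad)) {
    abort_conjseq(paste0("genes outside plasmid bounds: ",
                         paste(g$gene_id[bad], collapse = ", ")),
                  "conjseq_bad_genes")
  }
  samples <- dplyr::distinct(sites, .data$sample_id, .data$condition)
  per_gene <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    len <- gene_length(g$start[i], g$end[i], plasmid$length)
    lo <- floor(head_trim * len)       # offsets must exceed this
    hi <- ceiling((1 - tail_trim) * len)  # and not exceed this
    off <- gene_offset(sites$pos, g$start[i], g$end[i], g$strand[i],
                       plasmid$length)
    hit <- !is.na(off) & off > lo & off <= hi
    sites[hit, ] %>%
      dplyr::group_by(.data$sample_id, .data$condition) %>%
      dplyr::summarise(raw_count = sum(.data$count),
                       norm_count = sum(.data$norm_count), .groups = "drop") %>%
      dplyr::mutate(gene_id = g$gene_id[i])
  })
  samples %>%
    tidyr::expand_grid(gene_id = g$gene_id) %>%
    dplyr::left_join(per_gene, by = c("sample_id", "condition", "gene_id")) %>%
    dplyr::mutate(raw_count = dplyr::coalesce(.data$raw_count, 0L),
                  norm_count = dplyr::coalesce(.data$norm_count, 0)) %>%
    dplyr::select("gene_id", "sample_id", "condition", "raw_count",
                  "norm_count") %>%
    dplyr::arrange(.data$sample_id, .data$gene_id)
}

#' Depletion ratio of normalized gene counts between two libraries
#'
#' For each gene, `(norm_test - norm_initial) / norm_initial`: 0 means no
#' depletion, -1 complete depletion, positive values enrichment. Genes with a
#' zero initial count are undefined (`NA` ratio) — they cannot be
#' distinguished from unmappable regions and are never called.
#'
#' @param counts_test,counts_initial Tibbles with columns `gene_id` and
#'   `norm_count` over the same gene universe (e.g. one sample each from
#'   [gene_read_counts()]).
#' @return Tibble `gene_id`, `norm_test`, `norm_initial`, `ratio`.
#' @export
essentiality_ratio <- function(counts_test, counts_initial) {
  diff_ab <- setdiff(counts_test$gene_id, counts_initial$gene_id)
  diff_ba <- setdiff(counts_initial$gene_id, counts_test$gene_id)
  if (length(diff_ab) || length(diff_ba)) {
    abort_conjseq(
      paste0("gene universes differ; only in test: {",
             paste(diff_ab, collapse = ", "), "}; only in initial: {",
             paste(diff_ba, collapse = ", "), "}"),
      "conjseq_gene_mismatch"
    )
  }
  dplyr::inner_join(
    dplyr::select(counts_test, "gene_id", norm_test = "norm_count"),
    dplyr::select(counts_initial, "gene_id", norm_initial = "norm_count"),
    by = "gene_id"
  ) %>%
    dplyr::mutate(ratio = dplyr::if_else(
      .data$norm_initial > 0,
      (.data$norm_test - .data$norm_initial) / .data$norm_initial,
      NA_real_
    ))
}

#' Calibrate the essentiality threshold from a core gene set
#'
#' The threshold for a condition is the maximum depletion ratio observed over
#' a core set of genes known to be required in that condition (e.g. the T4SS
#' and relaxosome genes for in vitro transfer, the type IV pilus genes for
#' transfer in the gut).
#'
#' @param ratios Tibble with `gene_id` and `ratio` (e.g. from
#'   [essentiality_ratio()]), or a named numeric vector.
#' @param core Character vector of core gene ids (non-empty; every core gene
#'   must be present with a defined ratio).
#' @return The threshold (a single number).
#' @export
calibrate_threshold <- function(ratios, core) {
  if (length(core) == 0) {
    abort_conjseq("core gene set is empty", "conjseq_calibration_error")
  }
  if (!is.data.frame(ratios)) {
    ratios <- tibble(gene_id = names(ratios), ratio = as.numeric(ratios))
  }
  missing <- setdiff(core, ratios$gene_id)
  if (length(missing)) {
    abort_conjseq(paste0("core genes absent from ratio table: ",
                         paste(missing, collapse = ", ")),
                  "conjseq_calibration_error")
  }
  core_ratios <- ratios$ratio[match(core, ratios$gene_id)]
  if (any(is.na(core_ratios))) {
    abort_conjseq(
      paste0("core genes with no data (zero initial counts): ",
             paste(core[is.na(core_ratios)], collapse = ", ")),
      "conjseq_calibration_error"
    )
  }
  max(core_ratios)
}

#' Call gene essentiality against a calibrated threshold
#'
#' A gene is called essential when its ratio is less than or equal to the
#' threshold (inclusive, so every core gene is essential under its own
#' calibration); genes with undefined ratios are `no_data`.
#'
#' @param ratios Tibble with `gene_id` and `ratio`, or named numeric vector.
#' @param threshold Threshold from [calibrate_threshold()].
#' @return Input tibble with a `call` column
#'   (`essential`/`non_essential`/`no_data`).
#' @export
call_essential <- function(ratios, threshold) {
  if (!is.data.frame(ratios)) {
    ratios <- tibble(gene_id = names(ratios), ratio = as.numeric(ratios))
  }
  dplyr::mutate(ratios, call = dplyr::case_when(
    is.na(.data$ratio) ~ "no_data",
    .data$ratio <= threshold ~ "essential",
    TRUE ~ "non_essential"
  ))
}

#' Full essentiality analysis for one condition
#'
#' Pairs test-condition replicates with initial-library replicates (in order
#' within each condition), computes per-pair depletion ratios, averages them
#' per gene over pairs with data, calibrates the threshold on the core set
#' and calls essentiality.
#'
#' @param gene_counts Output of [gene_read_counts()] covering the initial and
#'   test conditions (replicates distinguished by `sample_id`).
#' @param test_condition Condition to analyse (e.g. `"invitro"`).
#' @param core Core gene ids used for calibration.
#' @param initial_condition Reference condition label (default `"initial"`).
#'
#' @return An object of class `essentiality_result`: list with `table` (a
#'   tibble `gene_id`, `ratio`, `n_pairs`, `call`), `threshold`, `core`,
#'   `condition`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
essentiality <- function(gene_counts, test_condition, core,
                         initial_condition = "initial") {
  have <- unique(gene_counts$condition)
  if (!all(c(test_condition, initial_condition) %in% have)) {
    abort_conjseq(
      sprintf("conditions %s and %s must both be present in gene_counts",
              test_condition, initial_condition),
      "conjseq_bad_input"
    )
  }
  test_samples <- sort(unique(
    gene_counts$sample_id[gene_counts$condition == test_condition]))
  init_samples <- sort(unique(
    gene_counts$sample_id[gene_counts$condition == initial_condition]))
  n_pairs <- min(length(test_samples), length(init_samples))
  pair_ratios <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    r <- essentiality_ratio(
      dplyr::filter(gene_counts, .data$sample_id == test_samples[k]),
      dplyr::filter(gene_counts, .data$sample_id == init_samples[k])
    )
    dplyr::mutate(r, pair = k)
  })
  tab <- pair_ratios %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      n_pairs = sum(!is.na(.data$ratio)),
      ratio = if (all(is.na(.data$ratio))) NA_real_ else
        mean(.data$ratio, na.rm = TRUE),
      .groups = "drop"
    )
  threshold <- calibrate_threshold(tab, core)
  tab <- call_essential(tab, threshold)
  structure(
    list(table = dplyr::select(tab, "gene_id", "ratio", "n_pairs", "call"),
         threshold = threshold, core = core, condition = test_condition),
    class = "essentiality_result"
  )
}

#' @export
print.essentiality_result <- function(x, ...) {
  counts <- table(factor(x$table$call,
                         c("essential", "non_essential", "no_data")))
  cat(sprintf(
    "<essentiality_result> condition %s: threshold %.4g (core n=%d); %d essential, %d non-essential, %d no-data\n",
    x$condition, x$threshold, length(x$core),
    counts[["essential"]], counts[["non_essential"]], counts[["no_data"]]
  ))
  invisible(x)
}

#' @export
tidy.essentiality_result <- function(x, ...) {
  dplyr::mutate(x$table, condition = x$condition, threshold = x$threshold,
                core_gene = .data$gene_id %in% x$core)
}

#' @export
glance.essentiality_result <- function(x, ...) {
  counts <- table(factor(x$table$call,
                         c("essential", "non_essential", "no_data")))
  tibble(condition = x$condition, threshold = x$threshold,
         n_genes = nrow(x$table),
         n_essential = counts[["essential"]],
         n_non_essential = counts[["non_essential"]],
         n_no_data = counts[["no_data"]],
         n_core = length(x$core))
}

#' @export
autoplot.essentiality_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_id, y = .data$ratio,
                                  fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "depletion ratio (test - initial) / initial",
      title = sprintf("Gene essentiality, %s (threshold %.3g)",
                      object$condition, object$threshold)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Screen for maintenance-essential genes in the initial library
#'
#' Maintenance genes (replication, partitioning, selection markers) never
#' appear in any library, so they cannot be scored by a ratio against the
#' initial library. They are flagged instead by insertion-site density: a
#' gene is called maintenance-essential when its trimmed-window site density
#' falls below `min_sites_per_kb`. At the study's insertion density (one site
#' per ~5 bp, i.e. ~200 sites/kb) the default of 10 sites/kb separates
#' depleted loci cleanly; regions of genuinely poor mappability will also
#' trigger the flag and need manual review.
#'
#' @param sites Normalized insertion-site tibble for initial-library
#'   replicate(s).
#' @param plasmid An `annotated_plasmid`.
#' @param min_sites_per_kb Density threshold (distinct sites per kb of
#'   counted gene window).
#' @inheritParams gene_read_counts
#' @return Tibble per gene: `gene_id`, `sites_per_kb` (mean over replicates),
#'   `call` (`essential`/`non_essential`).
#' @export
maintenance_screen <- function(sites, plasmid, min_sites_per_kb = 10,
                               head_trim = 0.05, tail_trim = 0.15) {
  g <- plasmid$genes
  per_sample <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    len <- gene_length(g$start[i], g$end[i], plasmid$length)
    lo <- floor(head_trim * len)
    hi <- ceiling((1 - tail_trim) * len)
    off <- gene_offset(sites$pos, g$start[i], g$end[i], g$strand[i],
                       plasmid$length)
    hit <- !is.na(off) & off > lo & off <= hi
    sites[hit, ] %>%
      dplyr::group_by(.data$sample_id) %>%
      dplyr::summarise(n_sites = dplyr::n(), .groups = "drop") %>%
      tidyr::complete(sample_id = unique(sites$sample_id),
                      fill = list(n_sites = 0L)) %>%
      dplyr::mutate(gene_id = g$gene_id[i],
                    sites_per_kb = .data$n_sites / ((hi - lo) / 1000))
  })
  per_sample %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(sites_per_kb = mean(.data$sites_per_kb),
                     .groups = "drop") %>%
    dplyr::mutate(call = dplyr::if_else(.data$sites_per_kb < min_sites_per_kb,
                                        "essential", "non_essential"))
}

#' Write a gene-level essentiality table to TSV
#'
#' @param x An `essentiality_result`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_essentiality_tsv <- function(x, path) {
  utils::write.table(tidy(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
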