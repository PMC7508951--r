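# Pan-genome classification of plasmid genes: global alignment identity,
# presence at identity cutoffs, core/soft-core/accessory categories and the
# intersection with essentiality calls.

#' Alignment scoring scheme
#'
#' Match/mismatch scores with a linear (per-base) gap cost. The defaults are
#' +1 per match and -2 per mismatch; the gap cost is a free parameter
#' (default -1 per gapped base).
#'
#' @param match Score per identical column (> 0).
#' @param mismatch Score per mismatched column (< 0).
#' @param gap Score per gapped base (< 0, linear in gap length).
#' @return List of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -2, gap = -1) {
  if (!(match > 0 && mismatch < 0 && gap < 0)) {
    abort_conjseq("need match > 0, mismatch < 0, gap < 0",
                  "conjseq_bad_scoring")
  }
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "align_scoring")
}

#' Optimal global alignment of two sequences
#'
#' Needleman-Wunsch dynamic programming under a linear gap model. Among
#' score-optimal alignments the one with the most match columns is returned,
#' so the derived percent identity is symmetric in the two sequences;
#' remaining ties are broken deterministically (match/mismatch over gaps,
#' then a gap in `a` over a gap in `b`).
#'
#' @param a,b Non-empty sequences (nucleotide or amino acid strings).
#' @param scoring An [align_scoring()].
#' @return Object of class `global_alignment`: list with `score`,
#'   `aligned_a`, `aligned_b` (gap character `-`), `scoring`.
#' @export
#' @examples
#' global_align("ACGT", "ACGT")$score  # 4
global_align <- function(a, b, scoring = align_scoring()) {
  if (!nzchar(a) || !nzchar(b)) {
    abort_conjseq("sequences must be non-empty", "conjseq_bad_input")
  }
  res <- .nw_align_cpp(toupper(a), toupper(b),
                       scoring$match, scoring$mismatch, scoring$gap)
  structure(c(res, list(scoring = scoring)), class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global_alignment> score %g, %d columns, identity %.1f%%\n",
              x$score, nchar(x$aligned_a), identity_pct(x)))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Percent identity of a global alignment
#'
#' The default (`method = "columns"`) is the fraction of alignment columns
#' that are identical residues, gap columns counted in the denominator. The
#' alternative (`method = "score"`) rescales the alignment score by the
#' maximum attainable score for the longer sequence, clamped at 0 — useful
#' when the identity notion should reward the same scoring that ranked the
#' alignment.
#'
#' @param alignment A `global_alignment`.
#' @param method `"columns"` (default) or `"score"`.
#' @return Identity percentage in `[0, 100]`.
#' @export
identity_pct <- function(alignment, method = c("columns", "score")) {
  method <- match.arg(method)
  a <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  if (method == "columns") {
    100 * sum(a == b & a != "-") / length(a)
  } else {
    s <- alignment$scoring
    n_res <- max(sum(a != "-"), sum(b != "-"))
    max(0, 100 * alignment$score / (s$match * n_res))
  }
}

#' Gene presence across a plasmid family at an identity cutoff
#'
#' For every annotated gene of the query plasmid, finds the best-scoring
#' global alignment against the annotated genes of each target plasmid (ties
#' broken by higher identity, then lexicographic target gene id) and records
#' presence when the best hit reaches `cutoff` percent identity.
#'
#' @param query An `annotated_plasmid` (e.g. the reference plasmid).
#' @param targets Non-empty list of `annotated_plasmid` targets.
#' @param cutoff Identity cutoff in percent, in `(0, 100]`; the conventional
#'   grid is 100, 70, 50.
#' @param mode `"nucleotide"` (default) or `"protein"` (align translated
#'   sequences).
#' @param scoring An [align_scoring()].
#' @param identity `"columns"` or `"score"`, see [identity_pct()].
#'
#' @return Object of class `presence_matrix`: tibble with one row per gene x
#'   target (`gene_id`, `target`, `best_hit`, `identity`, `aligned_length`,
#'   `present`), with attributes `cutoff`, `n_targets`.
#' @export
presence_matrix <- function(query, targets, cutoff = 70,
                            mode = c("nucleotide", "protein"),
                            scoring = align_scoring(),
                            identity = c("columns", "score")) {
  mode <- match.arg(mode)
  identity <- match.arg(identity)
  if (!length(targets)) {
    abort_conjseq("target list is empty", "conjseq_bad_input")
  }
  if (cutoff <= 0 || cutoff > 100) {
    abort_conjseq("cutoff must lie in (0, 100]", "conjseq_bad_input")
  }
  qseqs <- gene_sequences(query, mode)
  out <- purrr::map_dfr(targets, function(tg) {
    tseqs <- gene_sequences(tg, mode)
    tseqs <- tseqs[order(names(tseqs))]  # lexicographic tie-break
    purrr::map_dfr(names(qseqs), function(gid) {
      scores <- vapply(tseqs, function(ts) {
        .nw_score_cpp(qseqs[[gid]], ts, scoring$match, scoring$mismatch,
                      scoring$gap)
      }, numeric(1))
      best <- which(scores == max(scores))
      alns <- lapply(best, function(k) {
        global_align(qseqs[[gid]], tseqs[[k]], scoring)
      })
      idents <- vapply(alns, identity_pct, numeric(1), method = identity)
      pick <- best[order(-idents, names(tseqs)[best])][1]
      aln <- alns[[match(pick, best)]]
      ident_val <- identity_pct(aln, identity)
      tibble(
        gene_id = gid,
        target = tg$id,
        best_hit = names(tseqs)[pick],
        identity = ident_val,
        aligned_length = nchar(aln$aligned_a),
        present = ident_val >= cutoff
      )
    })
  })
  structure(out, class = c("presence_matrix", class(out)),
            cutoff = cutoff, n_targets = length(targets))
}

#' Gene presence at several identity cutoffs at once
#'
#' Computes the best-hit alignments once and thresholds them at each cutoff
#' (presence is monotone in the cutoff, so the hits can be shared).
#'
#' @inheritParams presence_matrix
#' @param cutoffs Numeric vector of identity cutoffs in percent.
#' @return Named list of `presence_matrix` objects, one per cutoff.
#' @export
presence_at_cutoffs <- function(query, targets, cutoffs = c(100, 70, 50),
                                mode = c("nucleotide", "protein"),
                                scoring = align_scoring(),
                                identity = c("columns", "score")) {
  base <- presence_matrix(query, targets, cutoff = min(cutoffs), mode = mode,
                          scoring = scoring, identity = identity)
  out <- lapply(cutoffs, function(cut) {
    m <- dplyr::mutate(as_tibble(base), present = .data$identity >= cut)
    structure(m, class = c("presence_matrix", class(m)),
              cutoff = cut, n_targets = attr(base, "n_targets"))
  })
  stats::setNames(out, paste0("cutoff_", cutoffs))
}

#' Categorize genes as core, soft-core or accessory
#'
#' A gene present in all plasmids of the family is core; present in more
#' than half (but not all), soft-core; otherwise accessory. Exactly half is
#' accessory, since soft-core requires strictly more than 50%.
#'
#' @param matrix A `presence_matrix`.
#' @return Tibble per gene: `gene_id`, `n_present`, `n_plasmids`, `fraction`,
#'   `category` (`core`/`soft_core`/`accessory`).
#' @export
categorize_genes <- function(matrix) {
  n_targets <- attr(matrix, "n_targets") %||%
    length(unique(matrix$target))
  matrix %>%
    as_tibble() %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(n_present = sum(.data$present), .groups = "drop") %>%
    dplyr::mutate(
      n_plasmids = n_targets,
      fraction = .data$n_present / n_targets,
      category = dplyr::case_when(
        .data$fraction == 1 ~ "core",
        .data$fraction > 0.5 ~ "soft_core",
        TRUE ~ "accessory"
      )
    )
}

#' Cross-tabulate pan-genome category with essentiality call
#'
#' Answers questions of the form "how many genes required for transfer in
#' the gut are part of the family core genome?".
#'
#' @param categories Output of [categorize_genes()].
#' @param essentiality An `essentiality_result` (or its [tidy()] tibble with
#'   `gene_id`, `call`, `condition`).
#' @return Tibble: `condition`, `category`, `call`, `n` (all category x call
#'   combinations, zero-filled).
#' @export
essentiality_overlap <- function(categories, essentiality) {
  ess <- if (inherits(essentiality, "essentiality_result")) {
    tidy(essentiality)
  } else {
    as_tibble(essentiality)
  }
  shared <- intersect(categories$gene_id, ess$gene_id)
  if (!length(shared)) {
    abort_conjseq("category and essentiality tables share no genes",
                  "conjseq_gene_mismatch")
  }
  dplyr::inner_join(
    dplyr::select(categories, "gene_id", "category"),
    dplyr::select(ess, "gene_id", "call", "condition"),
    by = "gene_id"
  ) %>%
    dplyr::count(.data$condition, .data$category, .data$call, name = "n") %>%
    tidyr::complete(
      condition = unique(ess$condition),
      category = c("core", "soft_core", "accessory"),
      call = c("essential", "non_essential", "no_data"),
      fill = list(n = 0L)
    )
}

#' @export
autoplot.presence_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$target, y = .data$gene_id,
                               fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(as_tibble(object),
                                             !.data$present),
                        shape = 4, size = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100),
                                  name = "% identity") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Gene presence at %g%% identity (x = absent)",
                      attr(object, "cutoff"))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
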