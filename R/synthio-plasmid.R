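# Synthetic annotated plasmids with ground-truth essentiality labels.

#' Construct an annotated plasmid object
#'
#' An annotated plasmid bundles a (usually circular) replicon sequence with a
#' gene table and, for synthetic data, the ground-truth essentiality labels
#' used to validate the analysis pipeline.
#'
#' @param id Plasmid identifier (used as the reference name in SAM/GFF3/FASTA).
#' @param sequence Nucleotide string over A/C/G/T.
#' @param genes Tibble with columns `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `product`. Coordinates are 1-based inclusive (GFF3
#'   convention). A wrap-around gene on a circular plasmid is encoded with
#'   `end < start`.
#' @param circular Is the replicon circular?
#' @param truth Optional ground truth, see [gen_plasmid()].
#'
#' @return An object of class `annotated_plasmid`: a list with elements `id`,
#'   `length`, `circular`, `sequence`, `genes` and `truth`.
#' @export
annotated_plasmid <- function(id, sequence, genes, circular = TRUE, truth = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.character(sequence))
  genes <- as_tibble(genes)
  needed <- c("gene_id", "start", "end", "strand")
  if (!all(needed %in% names(genes))) {
    abort_conjseq(
      paste0("gene table must have columns: ", paste(needed, collapse = ", ")),
      "conjseq_bad_genes"
    )
  }
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  len <- nchar(sequence)
  if (anyDuplicated(genes$gene_id)) {
    abort_conjseq("duplicate gene ids in gene table", "conjseq_bad_genes")
  }
  bad <- genes$start < 1L | genes$start > len | genes$end < 1L | genes$end > len
  if (any(bad)) {
    abort_conjseq(
      paste0("gene coordinates outside [1, ", len, "]: ",
             paste(genes$gene_id[bad], collapse = ", ")),
      "conjseq_bad_genes"
    )
  }
  if (!circular && any(genes$end < genes$start)) {
    abort_conjseq("wrap-around gene on a linear plasmid", "conjseq_bad_genes")
  }
  structure(
    list(id = id, length = len, circular = circular,
         sequence = sequence, genes = genes, truth = truth),
    class = "annotated_plasmid"
  )
}

#' @export
print.annotated_plasmid <- function(x, ...) {
  cat(sprintf("<annotated_plasmid> %s: %d bp%s, %d genes\n",
              x$id, x$length, if (x$circular) " (circular)" else "",
              nrow(x$genes)))
  if (!is.null(x$truth)) {
    cat(sprintf(
      "  truth: %d maintenance / %d in vitro / %d in situ essential; depletion %gx\n",
      length(x$truth$maintenance_essential),
      length(x$truth$invitro_essential),
      length(x$truth$insitu_essential),
      x$truth$depletion_factor
    ))
  }
  invisible(x)
}

#' Gene length in bp, handling wrap-around genes on circular plasmids
#' @noRd
gene_length <- function(start, end, plasmid_len) {
  ifelse(end >= start, end - start + 1L, plasmid_len - start + 1L + end)
}

#' Generate a synthetic annotated plasmid with known essentiality truth
#'
#' Builds a circular plasmid of non-overlapping genes separated by intergenic
#' spacers, and assigns each gene a ground-truth role mirroring the functional
#' classes of a conjugative plasmid: maintenance genes (replication,
#' partitioning, selection markers — required to keep the plasmid at all),
#' genes required for conjugative transfer in vitro (type IV secretion system
#' and relaxosome), and genes additionally required for transfer in the gut
#' (mating-pair stabilisation, e.g. a type IV pilus). At least one gene is
#' assigned to every class; remaining genes are non-essential cargo.
#'
#' @param n_genes Number of genes (>= 3 so each class is represented).
#' @param gene_len_range Length 2 vector, inclusive range of gene lengths (bp).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param spacer_range Inclusive range of intergenic spacer lengths (bp),
#'   minimum 10.
#' @param depletion_factor Fold reduction of insertion retention in an
#'   essential gene per selective passage; `Inf` means absolute depletion.
#' @param class_fractions Named numeric vector of target fractions of genes
#'   assigned to the `maintenance`, `invitro` and `insitu` classes.
#'
#' @return An `annotated_plasmid` whose `truth` element is a list with
#'   `maintenance_essential`, `invitro_essential`, `insitu_essential`
#'   (character vectors of gene ids; the in situ set lists genes needed *in
#'   addition to* the in vitro set, selection history being cumulative) and
#'   `depletion_factor`.
#' @export
#' @examples
#' p <- gen_plasmid(10, seed = 1)
#' p$genes
gen_plasmid <- function(n_genes,
                        gene_len_range = c(300, 1500),
                        seed = 1L,
                        spacer_range = c(10, 100),
                        depletion_factor = 1000,
                        class_fractions = c(maintenance = 0.2, invitro = 0.3,
                                            insitu = 0.2)) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 3) {
    abort_conjseq("n_genes must be a single number >= 3", "conjseq_sizing_error")
  }
  n_genes <- as.integer(n_genes)
  stopifnot(length(gene_len_range) == 2L, gene_len_range[1] >= 30,
            spacer_range[1] >= 10)
  with_substream(seed, "gen_plasmid", {
    gene_lens <- sample(seq(gene_len_range[1], gene_len_range[2]), n_genes,
                        replace = TRUE)
    spacers <- sample(seq(spacer_range[1], spacer_range[2]), n_genes,
                      replace = TRUE)
    total <- sum(gene_lens) + sum(spacers)
    if (total > 5e6) {
      abort_conjseq("requested plasmid exceeds 5 Mb; reduce n_genes",
                    "conjseq_sizing_error")
    }
    starts <- cumsum(c(spacers[1] + 1L,
                       gene_lens[-n_genes] + spacers[-1]))
    ends <- starts + gene_lens - 1L
    ids <- sprintf("gene%03d", seq_len(n_genes))

    # class assignment: at least one gene per class, sampled without overlap
    n_maint <- max(1L, round(class_fractions[["maintenance"]] * n_genes))
    n_vitro <- max(1L, round(class_fractions[["invitro"]] * n_genes))
    n_situ <- max(1L, round(class_fractions[["insitu"]] * n_genes))
    if (n_maint + n_vitro + n_situ > n_genes) {
      n_maint <- 1L
      n_situ <- 1L
      n_vitro <- n_genes - 2L
    }
    shuffled <- sample(ids)
    maint <- shuffled[seq_len(n_maint)]
    vitro <- shuffled[n_maint + seq_len(n_vitro)]
    situ <- shuffled[n_maint + n_vitro + seq_len(n_situ)]
    products <- rep("hypothetical protein", n_genes)
    products[ids %in% maint] <- "replication/maintenance protein"
    products[ids %in% vitro] <- "conjugative transfer protein (T4SS/relaxosome)"
    products[ids %in% situ] <- "type IV pilus protein (mating pair stabilization)"

    genes <- tibble(
      gene_id = ids,
      start = as.integer(starts),
      end = as.integer(ends),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      product = products
    )
    truth <- list(
      maintenance_essential = sort(maint),
      invitro_essential = sort(vitro),
      insitu_essential = sort(situ),
      depletion_factor = depletion_factor
    )
    annotated_plasmid(
      id = sprintf("pSYN%02d", abs(as.integer(seed)) %% 100),
      sequence = random_dna(total),
      genes = genes,
      circular = TRUE,
      truth = truth
    )
  })
}

#' Derive a synthetic plasmid family from a parent
#'
#' Emulates a family of related plasmids (e.g. members of one incompatibility
#' group) by copying the parent and applying, per child, per-gene loss and
#' per-base substitution and 1-bp indel mutations. Intergenic spacers are
#' mutated with the same rates. The realised expected per-gene sequence
#' identity, approximately `1 - sub_rate - indel_rate`, is recorded as truth.
#'
#' @param parent An `annotated_plasmid`.
#' @param n_children Number of derived plasmids.
#' @param sub_rate Per-base substitution probability in `[0, 1)`.
#' @param indel_rate Per-base probability of a 1-bp insertion or deletion
#'   (50/50), in `[0, 1)`.
#' @param loss_rate Per-gene deletion probability in `[0, 1]`.
#' @param seed Integer seed.
#'
#' @return List of `annotated_plasmid` children. Each child's `truth` holds
#'   `parent_id`, `retained_genes` and `expected_identity`.
#' @export
gen_plasmid_family <- function(parent, n_children, sub_rate = 0.02,
                               indel_rate = 0.002, loss_rate = 0.1,
                               seed = 1L) {
  stopifnot(inherits(parent, "annotated_plasmid"))
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1 ||
      loss_rate < 0 || loss_rate > 1) {
    abort_conjseq("mutation rates must lie in [0, 1)", "conjseq_bad_rate")
  }
  lapply(seq_len(n_children), function(k) {
    with_substream(seed, paste0("family_child_", k), {
      segs <- plasmid_segments(parent)
      keep_gene <- stats::runif(nrow(segs)) >= loss_rate | is.na(segs$gene_id)
      segs <- segs[keep_gene, , drop = FALSE]
      mutated <- vapply(segs$seq, mutate_seq, character(1),
                        sub_rate = sub_rate, indel_rate = indel_rate,
                        USE.NAMES = FALSE)
      lens <- nchar(mutated)
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      is_gene <- !is.na(segs$gene_id)
      genes <- tibble(
        gene_id = segs$gene_id[is_gene],
        start = as.integer(starts[is_gene]),
        end = as.integer(ends[is_gene]),
        strand = segs$strand[is_gene],
        product = segs$product[is_gene]
      )
      annotated_plasmid(
        id = sprintf("%s_child%02d", parent$id, k),
        sequence = paste(mutated, collapse = ""),
        genes = genes,
        circular = parent$circular,
        truth = list(
          parent_id = parent$id,
          retained_genes = genes$gene_id,
          expected_identity = 100 * (1 - sub_rate - indel_rate)
        )
      )
    })
  })
}

# Split a plasmid into an ordered tibble of gene and spacer segments
# (non-wrap-around genes only; generated plasmids never wrap).
plasmid_segments <- function(plasmid) {
  g <- dplyr::arrange(plasmid$genes, .data$start)
  if (any(g$end < g$start)) {
    abort_conjseq("wrap-around genes are not supported in family derivation",
                  "conjseq_bad_genes")
  }
  bounds <- c(0L, g$end)
  segs <- list()
  for (i in seq_len(nrow(g))) {
    sp_start <- bounds[i] + 1L
    if (sp_start < g$start[i]) {
      segs[[length(segs) + 1L]] <- tibble(
        gene_id = NA_character_, strand = NA_character_,
        product = NA_character_,
        seq = substr(plasmid$sequence, sp_start, g$start[i] - 1L)
      )
    }
    segs[[length(segs) + 1L]] <- tibble(
      gene_id = g$gene_id[i], strand = g$strand[i], product = g$product[i],
      seq = substr(plasmid$sequence, g$start[i], g$end[i])
    )
  }
  if (max(g$end) < plasmid$length) {
    segs[[length(segs) + 1L]] <- tibble(
      gene_id = NA_character_, strand = NA_character_, product = NA_character_,
      seq = substr(plasmid$sequence, max(g$end) + 1L, plasmid$length)
    )
  }
  dplyr::bind_rows(segs)
}

# Per-base substitution and 1-bp indel mutation of one sequence.
mutate_seq <- function(seq, sub_rate, indel_rate) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(bases)
  alphabet <- c("A", "C", "G", "T")
  subs <- which(stats::runif(n) < sub_rate)
  for (i in subs) {
    bases[i] <- sample(setdiff(alphabet, bases[i]), 1L)
  }
  indels <- which(stats::runif(n) < indel_rate)
  if (length(indels)) {
    # apply right-to-left so earlier positions stay valid
    for (i in rev(indels)) {
      if (stats::runif(1) < 0.5 && length(bases) > 1L) {
        bases <- bases[-i]
      } else {
        bases <- append(bases, sample(alphabet, 1L), after = i)
      }
    }
  }
  paste(bases, collapse = "")
}

#' Extract gene nucleotide (or protein) sequences from an annotated plasmid
#'
#' Returns each annotated gene's sequence on its coding strand; minus-strand
#' genes are reverse-complemented. `mode = "protein"` translates with the
#' standard code (partial trailing codons are dropped).
#'
#' @param plasmid An `annotated_plasmid`.
#' @param mode `"nucleotide"` or `"protein"`.
#' @return Named character vector, one element per gene.
#' @export
gene_sequences <- function(plasmid, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  g <- plasmid$genes
  seqs <- vapply(seq_len(nrow(g)), function(i) {
    if (g$end[i] >= g$start[i]) {
      s <- substr(plasmid$sequence, g$start[i], g$end[i])
    } else {
      if (!plasmid$circular) {
        abort_conjseq("wrap-around gene on linear plasmid", "conjseq_bad_genes")
      }
      s <- paste0(substr(plasmid$sequence, g$start[i], plasmid$length),
                  substr(plasmid$sequence, 1L, g$end[i]))
    }
    if (g$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  names(seqs) <- g$gene_id
  if (mode == "protein") {
    seqs <- vapply(seqs, function(s) {
      s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
      as.character(Biostrings::translate(Biostrings::DNAString(s),
                                         if.fuzzy.codon = "solve"))
    }, character(1))
  }
  seqs
}

#' Write a plasmid to FASTA and its annotation to GFF3
#'
#' @param plasmid An `annotated_plasmid`.
#' @param fasta,gff Output paths; `NULL` skips that file.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_plasmid <- function(plasmid, fasta = NULL, gff = NULL) {
  out <- character(0)
  if (!is.null(fasta)) {
    dna <- Biostrings::DNAStringSet(stats::setNames(plasmid$sequence, plasmid$id))
    Biostrings::writeXStringSet(dna, fasta)
    out["fasta"] <- fasta
  }
  if (!is.null(gff)) {
    g <- plasmid$genes
    # wrap-around genes are split at the origin for GFF3 conformance
    wraps <- g$end < g$start
    if (any(wraps)) {
      wrapped <- g[wraps, ]
      g <- dplyr::bind_rows(
        g[!wraps, ],
        dplyr::mutate(wrapped, end = plasmid$length),
        dplyr::mutate(wrapped, start = 1L)
      )
    }
    gr <- GenomicRanges::GRanges(
      seqnames = plasmid$id,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand
    )
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- g$gene_id
    S4Vectors::mcols(gr)$product <- g$product
    GenomeInfoDb::seqlengths(gr) <- plasmid$length
    rtracklayer::export(gr, gff, format = "gff3")
    out["gff"] <- gff
  }
  invisible(out)
}

#' Read an annotated plasmid from FASTA + GFF3
#'
#' @param fasta Single-record FASTA of the plasmid sequence.
#' @param gff GFF3 with `gene` features (1-based inclusive coordinates).
#' @param circular Is the replicon circular?
#' @return An `annotated_plasmid` (no truth).
#' @export
read_plasmid <- function(fasta, gff, circular = TRUE) {
  dna <- Biostrings::readDNAStringSet(fasta)
  if (length(dna) != 1L) {
    abort_conjseq("expected a single-record plasmid FASTA", "conjseq_bad_input")
  }
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "gene"]
  genes <- tibble(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = as.character(S4Vectors::mcols(gr)$product %||%
                             rep(NA_character_, length(gr)))
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  annotated_plasmid(
    id = sub("\\s.*$", "", names(dna)[1]),
    sequence = as.character(dna[[1]]),
    genes = genes,
    circular = circular
  )
}
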