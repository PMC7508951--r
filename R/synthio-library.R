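# Synthetic transposon insertion libraries, reads and alignments.

#' Simulation configuration for synthetic libraries and assays
#'
#' @param seed Integer; fixes all downstream randomness (each generator derives
#'   a deterministic substream from it).
#' @param n_insertions Number of distinct insertion sites per library. The
#'   default, 2000 sites on a ~10 kb plasmid, reproduces the study density of
#'   roughly one insertion every 5 bp.
#' @param mean_depth Mean reads per retained insertion site.
#' @param bottleneck_size Number of cells surviving the host-passage bottleneck
#'   applied before sequencing an in situ library.
#' @param mouse_cv Standard deviation of log10 CFU across replicate animals.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_insertions = 2000L, mean_depth = 50,
                       bottleneck_size = 1e5, mouse_cv = 0.5) {
  vals <- c(n_insertions = n_insertions, mean_depth = mean_depth,
            bottleneck_size = bottleneck_size, mouse_cv = mouse_cv)
  if (any(vals <= 0)) {
    abort_conjseq("all sim_config parameters must be positive",
                  "conjseq_bad_config")
  }
  structure(list(seed = as.integer(seed),
                 n_insertions = as.integer(n_insertions),
                 mean_depth = mean_depth,
                 bottleneck_size = as.integer(bottleneck_size),
                 mouse_cv = mouse_cv),
            class = "sim_config")
}

# Number of selective passages in which each gene is required, per condition.
# Selection history is cumulative: the in vitro library descends from the
# initial (maintenance-selected) library, and the in situ library from the
# in vitro transconjugants. A gene essential in k of the passages a library
# has been through is depleted by depletion_factor^k. Maintenance genes are
# required at every passage (the plasmid must replicate in each new host);
# T4SS/relaxosome genes at every transfer; mating-pair-stabilisation genes
# only at the in situ transfer.
passage_exponents <- function(truth, condition) {
  passages <- switch(condition,
    initial = list(truth$maintenance_essential),
    invitro = list(
      truth$maintenance_essential,
      union(truth$maintenance_essential, truth$invitro_essential)
    ),
    insitu = list(
      truth$maintenance_essential,
      union(truth$maintenance_essential, truth$invitro_essential),
      Reduce(union, truth[c("maintenance_essential", "invitro_essential",
                            "insitu_essential")])
    ),
    abort_conjseq(paste0("unknown condition: ", condition),
                  "conjseq_bad_condition")
  )
  genes <- unique(unlist(passages))
  stats::setNames(
    vapply(genes, function(g) sum(vapply(passages, function(s) g %in% s,
                                         logical(1))), integer(1)),
    genes
  )
}

# Map positions to the gene containing them (NA when intergenic).
position_gene <- function(pos, plasmid) {
  g <- plasmid$genes
  out <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(g))) {
    if (g$end[i] >= g$start[i]) {
      hit <- pos >= g$start[i] & pos <= g$end[i]
    } else {
      hit <- pos >= g$start[i] | pos <= g$end[i]
    }
    out[hit] <- g$gene_id[i]
  }
  out
}

#' Simulate a transposon insertion library for one selective condition
#'
#' Insertion positions are drawn uniformly (without replacement) over the
#' plasmid, excluding the four positions either side of the linearization
#' origin so that every site's 9-bp duplication is representable in a SAM
#' junction-read fixture. Selection history is cumulative (`initial` has
#' passed maintenance selection, `invitro` also an in vitro transfer,
#' `insitu` additionally a transfer in the gut), and `depletion_factor` acts
#' per selective passage: a mutant whose insertion sits in a gene essential
#' in `k` of the passages the library has been through is retained with
#' probability `(1/depletion_factor)^k` (zero when the factor is `Inf`). Read
#' counts per retained site are Poisson with mean `mean_depth`; zero-read
#' sites are unobserved. For `condition = "insitu"` a multinomial bottleneck
#' of `bottleneck_size` cells is applied first (see [bottleneck_subsample()])
#' and read counts are proportional to post-bottleneck clone abundance.
#'
#' @param plasmid An `annotated_plasmid`.
#' @param truth Ground truth as produced by [gen_plasmid()]; defaults to the
#'   plasmid's own.
#' @param condition One of `"initial"`, `"invitro"`, `"insitu"`.
#' @param cfg A [sim_config()].
#' @param sample_id Sample label written into the table (one replicate).
#'
#' @return Insertion-site tibble with columns `plasmid_id`, `sample_id`,
#'   `condition`, `pos`, `count`, `total_mapped` (`total_mapped` is constant
#'   within a sample).
#' @export
gen_insertion_library <- function(plasmid, truth = plasmid$truth,
                                  condition = c("initial", "invitro", "insitu"),
                                  cfg = sim_config(),
                                  sample_id = paste0(condition[1], "_rep1")) {
  condition <- match.arg(condition)
  stopifnot(inherits(plasmid, "annotated_plasmid"), !is.null(truth))
  exponents <- passage_exponents(truth, condition)
  bad <- setdiff(names(exponents), plasmid$genes$gene_id)
  if (length(bad)) {
    abort_conjseq(paste0("truth names unknown genes: ",
                         paste(bad, collapse = ", ")), "conjseq_bad_truth")
  }
  d <- truth$depletion_factor
  with_substream(cfg$seed, paste0("library_", condition, "_", sample_id), {
    # keep the 9-bp duplication fully inside the linearized reference so
    # every site is representable by a junction read in a SAM fixture
    valid <- seq(5L, plasmid$length - 4L)
    pos <- sort(sample(valid, min(cfg$n_insertions, length(valid))))
    gene_of <- position_gene(pos, plasmid)
    k <- ifelse(is.na(gene_of), 0L,
                unname(exponents[gene_of]))
    k[is.na(k)] <- 0L
    keep_p <- ifelse(k > 0, if (is.infinite(d)) 0 else (1 / d)^k, 1)
    pos <- pos[stats::runif(length(pos)) < keep_p]
    if (condition == "insitu") {
      cells <- bottleneck_subsample(pos, cfg$bottleneck_size)
      pos <- cells$pos
      # expected read depth proportional to clone abundance, mean = mean_depth
      lam <- cfg$mean_depth * cells$cells * length(pos) / sum(cells$cells)
    } else {
      lam <- rep(cfg$mean_depth, length(pos))
    }
    count <- stats::rpois(length(pos), lam)
    keep <- count > 0
    tibble(
      plasmid_id = plasmid$id,
      sample_id = sample_id,
      condition = condition,
      pos = as.integer(pos[keep]),
      count = as.integer(count[keep]),
      total_mapped = sum(count[keep])
    )
  })
}

#' Multinomial bottleneck subsampling of insertion clones
#'
#' Draws `size` surviving cells from the clone pool (uniform over clones, as
#' for a neutral bottleneck) and returns the clones observed at least once.
#' Cell counts sum to `size` exactly.
#'
#' @param pos Integer vector of insertion positions (one clone each).
#' @param size Bottleneck size (cells).
#' @return Tibble with columns `pos` and `cells` (`sum(cells) == size`).
#' @export
bottleneck_subsample <- function(pos, size) {
  stopifnot(length(pos) > 0, size >= 1)
  cells <- as.integer(stats::rmultinom(1, size, rep(1, length(pos)))[, 1])
  tibble(pos = pos[cells > 0], cells = cells[cells > 0])
}

#' Generate a full multi-condition, multi-replicate insertion experiment
#'
#' Convenience wrapper around [gen_insertion_library()] mirroring the study
#' design: an initial (maintenance-selected) library and libraries after
#' in vitro and in situ conjugative transfer, each in replicate.
#'
#' @inheritParams gen_insertion_library
#' @param conditions Conditions to simulate.
#' @param n_reps Replicates per condition.
#' @return One insertion-site tibble (rows from all samples bound together).
#' @export
gen_hdtm_experiment <- function(plasmid, truth = plasmid$truth,
                                conditions = c("initial", "invitro", "insitu"),
                                n_reps = 3L, cfg = sim_config()) {
  purrr::map_dfr(conditions, function(cond) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      gen_insertion_library(plasmid, truth, cond, cfg,
                            sample_id = sprintf("%s_rep%d", cond, r))
    })
  })
}

#' Emit sequencing reads and alignments for an insertion-site table
#'
#' For every insertion site, emits `count` transposon-junction reads whose
#' alignment encodes the site under the 9-bp target-site duplication
#' convention used by [call_insertion_sites()]: a forward alignment starts at
#' the first base of the duplication (site − 4); a reverse alignment ends at
#' its last base (site + 4). Read orientation is random where both fit on the
#' reference. Writes a FASTQ of the reads and a minimal single-reference SAM
#' (mandatory columns + MAPQ).
#'
#' @param table Insertion-site tibble for a single sample.
#' @param plasmid The `annotated_plasmid` the sites refer to.
#' @param read_len Read length (>= 30 bp, <= plasmid length).
#' @param seed Integer seed.
#' @param lowq_frac Fraction of reads downgraded to MAPQ 20 (below the
#'   calling threshold).
#' @param n_noise Number of injected spurious singleton sites (1 read each),
#'   emulating residual sequencing noise.
#' @param fastq,sam Output paths (defaults under `tempdir()`).
#'
#' @return Invisibly, list with `fastq`, `sam` and the tibble of simulated
#'   read alignments.
#' @export
gen_reads <- function(table, plasmid, read_len = 50L, seed = 1L,
                      lowq_frac = 0, n_noise = 0L,
                      fastq = tempfile(fileext = ".fastq"),
                      sam = tempfile(fileext = ".sam")) {
  if (read_len < 30L) {
    abort_conjseq("read_len must be >= 30", "conjseq_bad_input")
  }
  if (read_len > plasmid$length) {
    abort_conjseq("read longer than plasmid", "conjseq_bad_input")
  }
  stopifnot(all(table$pos >= 1), all(table$pos <= plasmid$length))
  with_substream(seed, "gen_reads", {
    pos <- rep(table$pos, table$count)
    if (n_noise > 0) {
      noise_pos <- sample.int(plasmid$length, n_noise)
      pos <- c(pos, noise_pos)
    }
    n <- length(pos)
    # orientation: forward needs site - 4 >= 1 and site - 4 + L - 1 <= len;
    # reverse needs site + 4 <= len and site + 4 - L + 1 >= 1
    fwd_ok <- (pos - 4L) >= 1L & (pos - 4L + read_len - 1L) <= plasmid$length
    rev_ok <- (pos + 4L) <= plasmid$length & (pos + 4L - read_len + 1L) >= 1L
    use_fwd <- ifelse(fwd_ok & rev_ok, stats::runif(n) < 0.5, fwd_ok)
    if (any(!fwd_ok & !rev_ok)) {
      abort_conjseq("plasmid too short to place reads for some sites",
                    "conjseq_bad_input")
    }
    start <- ifelse(use_fwd, pos - 4L, pos + 4L - read_len + 1L)
    end <- start + read_len - 1L
    mapq <- rep(60L, n)
    if (lowq_frac > 0) {
      mapq[stats::runif(n) < lowq_frac] <- 20L
    }
    seqs <- substring(plasmid$sequence, start, end)
    read_seq <- seqs
    if (any(!use_fwd)) {
      read_seq[!use_fwd] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[!use_fwd])))
    }
    qname <- sprintf("read%06d_pos%d", seq_len(n), pos)
    qual <- strrep("I", read_len)

    fq <- Biostrings::DNAStringSet(stats::setNames(read_seq, qname))
    Biostrings::writeXStringSet(
      fq, fastq, format = "fastq",
      qualities = Biostrings::BStringSet(rep(qual, n))
    )
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", plasmid$id, plasmid$length))
    records <- sprintf(
      "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
      qname, ifelse(use_fwd, 0L, 16L), plasmid$id, start, mapq,
      read_len, read_seq, qual
    )
    writeLines(c(header, records), sam)
    invisible(list(
      fastq = fastq, sam = sam,
      alignments = tibble(qname = qname, pos = as.integer(start),
                          end = as.integer(end),
                          strand = ifelse(use_fwd, "+", "-"),
                          mapq = mapq, site = as.integer(pos))
    ))
  })
}
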