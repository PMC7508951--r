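# Read trimming and insertion-site calling from alignments.

#' Quality-trim reads with a sliding window
#'
#' Scans each read 5' to 3' with a window of `window` bases and cuts the read
#' at the first window whose mean Phred quality falls below
#' `min_mean_quality`; within that window, leading bases individually at or
#' above the threshold are still kept (so the cut lands on the first
#' low-quality base). Reads shorter than `min_length` after cutting are
#' dropped. Defaults correspond to the Trimmomatic settings
#' `SLIDINGWINDOW:4:20` and `MINLEN:30`.
#'
#' @param reads Path to a FASTQ file (Phred+33 qualities) or a
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param window Window width in bases.
#' @param min_mean_quality Minimum mean Phred quality per window.
#' @param min_length Minimum read length kept after trimming.
#' @param out Optional output FASTQ path.
#'
#' @return A [Biostrings::QualityScaledDNAStringSet] of surviving reads
#'   (written to `out` when given), with attribute `n_dropped`.
#' @export
trim_reads <- function(reads, window = 4L, min_mean_quality = 20,
                       min_length = 30L, out = NULL) {
  if (is.character(reads)) {
    path <- reads
    # structural validation first: the Biostrings reader silently pads
    # records whose quality string is shorter than the sequence
    lines <- readLines(path, warn = FALSE)
    bad_at <- function(i, what) {
      abort_conjseq(sprintf("malformed FASTQ (%s), record %d: %s",
                            basename(path), i, what), "conjseq_parse_error")
    }
    if (length(lines) %% 4 != 0) {
      abort_conjseq(sprintf("malformed FASTQ (%s): truncated record",
                            basename(path)), "conjseq_parse_error")
    }
    for (i in seq_len(length(lines) %/% 4)) {
      rec <- lines[(i - 1) * 4 + 1:4]
      if (!startsWith(rec[1], "@")) bad_at(i, "missing @ header")
      if (!startsWith(rec[3], "+")) bad_at(i, "missing + separator")
      if (nchar(rec[2]) != nchar(rec[4])) {
        bad_at(i, "sequence and quality lengths differ")
      }
    }
    reads <- tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) {
        abort_conjseq(paste0("malformed FASTQ (", basename(path), "): ",
                             conditionMessage(e)), "conjseq_parse_error")
      }
    )
  }
  stopifnot(methods::is(reads, "QualityScaledDNAStringSet"))
  quals <- methods::as(Biostrings::quality(reads), "IntegerList")
  lens <- Biostrings::width(reads)
  cut_at <- vapply(seq_along(reads), function(i) {
    q <- quals[[i]]
    n <- length(q)
    if (n < window) return(n)
    means <- (cumsum(q)[window:n] -
                c(0, cumsum(q))[1:(n - window + 1L)]) / window
    bad <- which(means < min_mean_quality)
    if (length(bad) == 0) return(n)
    end <- bad[1] - 1L
    # keep leading bases of the failing window that individually pass
    while (end < n && q[end + 1L] >= min_mean_quality) end <- end + 1L
    end
  }, integer(1))
  trimmed <- IRanges::narrow(reads, start = 1L, end = cut_at)
  keep <- Biostrings::width(trimmed) >= min_length
  result <- trimmed[keep]
  attr(result, "n_dropped") <- sum(!keep)
  if (!is.null(out)) {
    Biostrings::writeXStringSet(methods::as(result, "DNAStringSet"), out,
                                format = "fastq",
                                qualities = methods::as(
                                  Biostrings::quality(result), "BStringSet"))
  }
  result
}

#' Call transposon insertion sites from alignments
#'
#' Reads a SAM/BAM of transposon-junction reads aligned to the plasmid,
#' discards unmapped records and records with mapping quality below
#' `mapq_min`, and converts each surviving alignment to the canonical
#' insertion coordinate: the middle base of the 9-bp Tn5 target-site
#' duplication. A forward alignment starts at the first duplicated base, so
#' its site is `start + 4`; a reverse alignment ends at the last duplicated
#' base, so its site is `end - 4`. Sites supported by a single read are
#' removed as sequencing noise.
#'
#' @param alignments Path to a SAM or BAM file whose only reference is the
#'   plasmid (host-chromosome reads must already be excluded).
#' @param plasmid An `annotated_plasmid`; the SAM reference name must match
#'   `plasmid$id`.
#' @param mapq_min Minimum mapping quality retained.
#' @param sample_id,condition Labels copied into the output table.
#'
#' @return Insertion-site tibble (`plasmid_id`, `sample_id`, `condition`,
#'   `pos`, `count`, `total_mapped`). `total_mapped` counts all reads passing
#'   the mapping-quality filter, before singleton-site removal.
#' @export
call_insertion_sites <- function(alignments, plasmid, mapq_min = 30L,
                                 sample_id = "sample1",
                                 condition = NA_character_) {
  stopifnot(inherits(plasmid, "annotated_plasmid"))
  bam <- if (grepl("\\.bam$", alignments, ignore.case = TRUE)) {
    alignments
  } else {
    Rsamtools::asBam(alignments,
                     destination = tempfile(),
                     overwrite = TRUE, indexDestination = FALSE)
  }
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = "mapq")
  )
  refs <- as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(aln)))
  if (!identical(refs, plasmid$id)) {
    abort_conjseq(
      sprintf("SAM reference (%s) does not match plasmid id (%s)",
              paste(refs, collapse = ","), plasmid$id),
      "conjseq_ref_mismatch"
    )
  }
  mapq <- S4Vectors::mcols(aln)$mapq
  aln <- aln[!is.na(mapq) & mapq >= mapq_min]
  total <- length(aln)
  fwd <- as.character(BiocGenerics::strand(aln)) != "-"
  site <- ifelse(fwd,
                 BiocGenerics::start(aln) + 4L,
                 BiocGenerics::end(aln) - 4L)
  if (any(BiocGenerics::start(aln) < 1L)) {
    abort_conjseq("negative or zero alignment positions", "conjseq_bad_input")
  }
  if (any(site < 1L | site > plasmid$length) && !plasmid$circular) {
    abort_conjseq("insertion site outside a linear plasmid",
                  "conjseq_bad_input")
  }
  site <- ((site - 1L) %% plasmid$length) + 1L
  counts <- table(site)
  pos <- as.integer(names(counts))
  count <- as.integer(counts)
  keep <- count >= 2L
  tibble(
    plasmid_id = plasmid$id,
    sample_id = sample_id,
    condition = condition,
    pos = pos[keep],
    count = count[keep],
    total_mapped = total
  ) %>% dplyr::arrange(.data$pos)
}

#' Depth-normalize insertion-site read counts
#'
#' Adds a `norm_count` column scaling each site count to counts per million
#' mapped reads (`count * 1e6 / total_mapped`), so libraries sequenced to
#' different depths are comparable. Raw counts are retained.
#'
#' @param sites Insertion-site tibble (one or many samples; normalization is
#'   per `sample_id` via each row's `total_mapped`).
#' @param reference_depth Depth unit; default 1e6 (counts per million).
#' @return The input tibble with a `norm_count` column.
#' @export
normalize_depth <- function(sites, reference_depth = 1e6) {
  if (any(sites$total_mapped == 0)) {
    abort_conjseq("total_mapped is zero for some sample; cannot normalize",
                  "conjseq_zero_depth")
  }
  dplyr::mutate(sites, norm_count = .data$count * reference_depth /
                  .data$total_mapped)
}

#' Export an insertion map as a bedGraph track
#'
#' Writes one 0-based half-open interval of width 1 per insertion site with
#' the normalized count as the track value, sorted by position — the format
#' used for genome-browser visualization of insertion maps.
#'
#' @param sites Normalized insertion-site tibble for a single sample (needs
#'   `norm_count`; run [normalize_depth()] first).
#' @param path Output bedGraph path.
#' @return Invisibly, `path`.
#' @export
export_insertion_track <- function(sites, path) {
  if (!"norm_count" %in% names(sites)) {
    abort_conjseq("sites table lacks norm_count; run normalize_depth() first",
                  "conjseq_bad_input")
  }
  if (length(unique(sites$sample_id)) > 1) {
    abort_conjseq("export one sample at a time", "conjseq_bad_input")
  }
  header <- sprintf("track type=bedGraph name=\"%s\"",
                    if (nrow(sites)) sites$sample_id[1] else "insertions")
  sites <- dplyr::arrange(sites, .data$pos)
  values <- vapply(sites$norm_count, format, character(1),
                   trim = TRUE, scientific = FALSE)
  lines <- sprintf("%s\t%d\t%d\t%s", sites$plasmid_id, sites$pos - 1L,
                   sites$pos, values)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Import a bedGraph insertion track
#'
#' Inverse of [export_insertion_track()] up to the raw-count columns.
#'
#' @param path bedGraph path.
#' @param sample_id,condition Labels for the rebuilt table.
#' @return Tibble with `plasmid_id`, `sample_id`, `condition`, `pos`,
#'   `norm_count`.
#' @export
import_insertion_track <- function(path, sample_id = NA_character_,
                                   condition = NA_character_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    plasmid_id = as.character(GenomeInfoDb::seqnames(gr)),
    sample_id = sample_id,
    condition = condition,
    pos = GenomicRanges::start(gr),
    norm_count = as.numeric(S4Vectors::mcols(gr)$score)
  ) %>% dplyr::arrange(.data$pos)
}
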