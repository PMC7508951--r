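# Fixtures built in code: toy plasmids, crafted SAM files, quality-scaled
# reads. Everything is deterministic.

toy_plasmid <- function(len = 300, genes = NULL, id = "pTOY", seed = 99,
                        circular = TRUE) {
  seq <- withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = "geneA", start = 1L, end = 100L,
                            strand = "+", product = NA_character_)
  }
  annotated_plasmid(id = id, sequence = seq, genes = genes,
                    circular = circular)
}

# Minimal SAM writer for crafted alignment cases. `df` columns: pos, strand
# ("+"/"-"), mapq; optional read_len (default 50).
write_toy_sam <- function(plasmid, df, path = tempfile(fileext = ".sam"),
                          read_len = 50L) {
  start <- ifelse(df$strand == "+", df$pos, df$pos - read_len + 1L)
  seqs <- substring(plasmid$sequence, start, start + read_len - 1L)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", plasmid$id, plasmid$length),
    sprintf("r%03d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
            seq_len(nrow(df)), ifelse(df$strand == "+", 0L, 16L),
            plasmid$id, start, df$mapq, read_len, seqs,
            strrep("I", read_len))
  )
  writeLines(lines, path)
  path
}

# Quality-scaled reads from explicit per-base Phred vectors.
make_reads <- function(quals, seed = 7) {
  seqs <- withr::with_seed(seed, vapply(lengths(quals), function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1)))
  qstr <- vapply(quals, function(q) {
    rawToChar(as.raw(q + 33L))
  }, character(1))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, paste0("r", seq_along(quals)))),
    Biostrings::PhredQuality(qstr)
  )
}

# Toy gene-count table for exact ratio arithmetic.
toy_counts <- function(norm, sample_id, condition) {
  tibble::tibble(gene_id = names(norm), sample_id = sample_id,
                 condition = condition, raw_count = as.integer(norm),
                 norm_count = as.numeric(norm))
}
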