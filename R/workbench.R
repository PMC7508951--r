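# Pipeline orchestration: configuration, input validation, a reproducible
# end-to-end demonstration run and its manifest.

default_config <- function() {
  list(
    seed = 42L,
    n_genes = 12L,
    n_insertions = 1000L,
    mean_depth = 30,
    bottleneck_size = 50000L,
    mouse_cv = 0.5,
    depletion_factor = 1000,
    mapq_min = 30L,
    head_trim = 0.05,
    tail_trim = 0.15,
    cutoffs = c(100, 70, 50),
    gap = -1,
    n_children = 7L,
    sub_rate = 0.02,
    indel_rate = 0.002,
    loss_rate = 0.15,
    n_reps = 3L,
    n_mice = 4L,
    true_rate_efficient = 1e-2,
    true_rate_poor = 1e-6
  )
}

#' Read a pipeline configuration file
#'
#' Reads a JSON (or YAML, by extension) configuration and merges it over the
#' package defaults. Unknown keys are rejected so typos cannot silently fall
#' back to defaults.
#'
#' @param path Path to a `.json`/`.yaml`/`.yml` file, or `NULL` for the
#'   defaults.
#' @return Named list of pipeline parameters.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    abort_conjseq(paste0("unknown configuration keys: ",
                         paste(unknown, collapse = ", ")),
                  "conjseq_bad_config")
  }
  utils::modifyList(cfg, user)
}

#' Validate pipeline input files
#'
#' Checks FASTA/GFF3/SAM/CSV inputs for conformance before a run: parseable
#' files, unique identifiers, gene coordinates within the replicon, SAM
#' references matching the FASTA, and the expected spot-assay columns with
#' non-negative counts.
#'
#' @param fasta,gff,sam,csv Optional file paths; only supplied files are
#'   checked (the GFF3 and SAM checks need `fasta` for reference lengths).
#' @return Tibble of diagnostics (`file`, `item`, `message`); zero rows means
#'   all supplied inputs passed.
#' @export
validate_inputs <- function(fasta = NULL, gff = NULL, sam = NULL, csv = NULL) {
  diags <- list()
  note <- function(file, item, message) {
    diags[[length(diags) + 1L]] <<- tibble(file = file, item = item,
                                           message = message)
  }
  seq_lens <- NULL
  if (!is.null(fasta)) {
    dna <- tryCatch(Biostrings::readDNAStringSet(fasta), error = function(e) {
      note(fasta, NA_character_, paste0("unreadable FASTA: ",
                                        conditionMessage(e)))
      NULL
    })
    if (!is.null(dna)) {
      ids <- sub("\\s.*$", "", names(dna))
      if (anyDuplicated(ids)) {
        note(fasta, ids[duplicated(ids)][1], "duplicate sequence id")
      }
      seq_lens <- stats::setNames(Biostrings::width(dna), ids)
    }
  }
  if (!is.null(gff)) {
    gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                   error = function(e) {
                     note(gff, NA_character_, paste0("unreadable GFF3: ",
                                                     conditionMessage(e)))
                     NULL
                   })
    if (!is.null(gr)) {
      ids <- as.character(S4Vectors::mcols(gr)$ID)
      if (anyDuplicated(stats::na.omit(ids))) {
        note(gff, ids[duplicated(ids) & !is.na(ids)][1], "duplicate feature ID")
      }
      if (!is.null(seq_lens)) {
        chrom <- as.character(GenomeInfoDb::seqnames(gr))
        unknown <- !chrom %in% names(seq_lens)
        for (i in which(unknown)) {
          note(gff, ids[i] %||% NA_character_,
               paste0("feature on unknown sequence ", chrom[i]))
        }
        over <- !unknown & GenomicRanges::end(gr) > seq_lens[chrom]
        for (i in which(over)) {
          note(gff, ids[i],
               sprintf("feature end %d beyond sequence length %d",
                       GenomicRanges::end(gr)[i], seq_lens[chrom[i]]))
        }
      }
    }
  }
  if (!is.null(sam)) {
    lines <- readLines(sam, warn = FALSE)
    sq <- grep("^@SQ", lines, value = TRUE)
    refs <- sub(".*SN:([^\t]+).*", "\\1", sq)
    if (!is.null(seq_lens)) {
      for (r in setdiff(refs, names(seq_lens))) {
        note(sam, r, "SAM reference absent from FASTA")
      }
    }
    body <- lines[!startsWith(lines, "@")]
    if (length(body)) {
      fields <- strsplit(body, "\t", fixed = TRUE)
      nf <- lengths(fields)
      for (i in which(nf < 11)) {
        note(sam, paste0("line ", i + length(lines) - length(body)),
             "SAM record with fewer than 11 mandatory fields")
      }
      rn <- vapply(fields[nf >= 11], `[[`, character(1), 3L)
      bad <- !rn %in% c("*", refs)
      for (i in which(bad)) {
        note(sam, rn[i], "record maps to reference not declared in header")
      }
    }
  }
  if (!is.null(csv)) {
    df <- tryCatch(utils::read.csv(csv), error = function(e) {
      note(csv, NA_character_, paste0("unreadable CSV: ",
                                      conditionMessage(e)))
      NULL
    })
    if (!is.null(df)) {
      needed <- c("selection", "dilution_exponent", "spot_volume_uL",
                  "colonies")
      miss <- setdiff(needed, names(df))
      if (length(miss)) {
        note(csv, NA_character_,
             paste0("missing columns: ", paste(miss, collapse = ", ")))
      }
      if ("colonies" %in% names(df) && any(df$colonies < 0, na.rm = TRUE)) {
        note(csv, "colonies", "negative colony counts")
      }
      if ("selection" %in% names(df)) {
        bad <- setdiff(unique(df$selection),
                       c("donor", "recipient", "transconjugant"))
        if (length(bad)) {
          note(csv, bad[1], "unknown selection label")
        }
      }
    }
  }
  if (length(diags)) dplyr::bind_rows(diags) else
    tibble(file = character(), item = character(), message = character())
}

#' Run a complete synthetic demonstration study
#'
#' Generates a synthetic annotated plasmid, a three-condition (initial /
#' in vitro / in situ) replicated insertion experiment, conjugation spot
#' assays for an efficient and a poor plasmid, and a plasmid family; then
#' runs every analysis stage: insertion-site normalization, gene counts,
#' maintenance screen, essentiality per condition (calibrated on the true
#' core sets), transfer rates with censoring, fold change and log-scale
#' ANOVA, pan-genome categories at the 100/70/50 cutoffs and their overlap
#' with essentiality. All outputs are written under `dir` together with a run
#' manifest; a fixed seed reproduces the output tree byte for byte.
#'
#' @param seed Integer seed (overrides the config seed).
#' @param dir Output directory (created if needed).
#' @param config Pipeline configuration, see [read_pipeline_config()].
#' @return Invisibly, a list with the main in-memory results (`plasmid`,
#'   `gene_counts`, `maintenance`, `essentiality`, `rates`, `fold`,
#'   `anova`, `categories`, `overlap`, `manifest`).
#' @export
run_demo <- function(seed = 42L, dir = tempfile("conjseq_demo"),
                     config = read_pipeline_config()) {
  t0 <- Sys.time()
  config$seed <- as.integer(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path

  plasmid <- gen_plasmid(config$n_genes, seed = config$seed,
                         depletion_factor = config$depletion_factor)
  write_plasmid(plasmid, fasta = p(dir, "plasmid.fasta"),
                gff = p(dir, "plasmid.gff3"))
  scfg <- sim_config(seed = config$seed, n_insertions = config$n_insertions,
                     mean_depth = config$mean_depth,
                     bottleneck_size = config$bottleneck_size,
                     mouse_cv = config$mouse_cv)
  sites <- gen_hdtm_experiment(plasmid, n_reps = config$n_reps, cfg = scfg) %>%
    normalize_depth()
  # demonstrate the SAM round trip on one replicate
  rep1 <- dplyr::filter(sites, .data$sample_id == "initial_rep1")
  rt <- gen_reads(rep1, plasmid, seed = config$seed,
                  fastq = p(dir, "initial_rep1.fastq"),
                  sam = p(dir, "initial_rep1.sam"))
  called <- call_insertion_sites(rt$sam, plasmid, config$mapq_min,
                                 sample_id = "initial_rep1",
                                 condition = "initial")
  export_insertion_track(normalize_depth(called),
                         p(dir, "initial_rep1.bedGraph"))

  counts <- gene_read_counts(sites, plasmid, config$head_trim,
                             config$tail_trim)
  maint <- maintenance_screen(
    dplyr::filter(sites, .data$condition == "initial"), plasmid
  )
  ess <- list(
    invitro = essentiality(counts, "invitro",
                           core = plasmid$truth$invitro_essential),
    insitu = essentiality(counts, "insitu",
                          core = plasmid$truth$insitu_essential)
  )
  ess_tab <- dplyr::bind_rows(lapply(ess, tidy))
  utils::write.table(ess_tab, p(dir, "essentiality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(maint, p(dir, "maintenance_screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  assays <- dplyr::bind_rows(
    efficient = gen_cfu_assay(true_rate = config$true_rate_efficient,
                              n_mice = config$n_mice, cfg = scfg),
    poor = gen_cfu_assay(true_rate = config$true_rate_poor,
                         n_mice = config$n_mice,
                         cfg = sim_config(seed = config$seed + 1L,
                                          mouse_cv = config$mouse_cv)),
    .id = "plasmid"
  )
  utils::write.csv(assays, p(dir, "spot_assays.csv"), row.names = FALSE)
  rates <- transfer_rates(assays)
  utils::write.table(rates, p(dir, "transfer_rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  eff <- dplyr::filter(rates, .data$plasmid == "efficient")
  poor <- dplyr::filter(rates, .data$plasmid == "poor")
  # poor plasmid relative to the efficient one; censored animals keep the
  # fold change an upper bound, as when LOD values substitute for non-detects
  fold <- fold_change(poor, eff)
  anova <- anova_log(rates$value, rates$plasmid)
  summ <- rate_summary(rates, rates$plasmid)
  utils::write.table(summ, p(dir, "rate_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  family <- gen_plasmid_family(plasmid, config$n_children,
                               sub_rate = config$sub_rate,
                               indel_rate = config$indel_rate,
                               loss_rate = config$loss_rate,
                               seed = config$seed)
  cats <- purrr::map(
    presence_at_cutoffs(plasmid, family, cutoffs = config$cutoffs,
                        scoring = align_scoring(gap = config$gap)),
    categorize_genes
  )
  cat_tab <- dplyr::bind_rows(cats, .id = "cutoff")
  utils::write.table(cat_tab, p(dir, "pangenome_categories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  overlap <- essentiality_overlap(cats[[2]], ess$insitu)
  utils::write.table(overlap, p(dir, "essentiality_overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  outputs <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(
    tool = "conjseq",
    version = as.character(utils::packageVersion("conjseq")),
    config_hash = content_hash(cfg_json),
    input_checksums = stats::setNames(
      lapply(outputs[grepl("fasta|gff3|csv$", outputs)], function(f) {
        content_hash(readLines(p(dir, f), warn = FALSE))
      }),
      outputs[grepl("fasta|gff3|csv$", outputs)]
    ),
    record_counts = list(
      insertion_sites = nrow(sites),
      called_sites_rep1 = nrow(called),
      gene_counts = nrow(counts),
      transfer_rates = nrow(rates),
      pangenome_rows = nrow(cat_tab)
    ),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, p(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(plasmid = plasmid, sites = sites, gene_counts = counts,
                 maintenance = maint, essentiality = ess, rates = rates,
                 fold = fold, anova = anova, categories = cats,
                 overlap = overlap, manifest = manifest, dir = dir))
}
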