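# Synthetic serial-dilution conjugation assays.

#' Simulate serial-dilution spot assays for a conjugation experiment
#'
#' Emulates the standard workflow: per animal (or culture), donor and
#' recipient abundances vary log-normally around their true values
#' (`sd = mouse_cv` on the log10 scale); the expected transconjugant
#' abundance is `recipient * true_rate`; each selection is serially diluted
#' 1/10 and `n_spots` replicate spots per dilution are plated, with colony
#' counts drawn as Poisson from the expected CFU in the spotted volume.
#'
#' @param true_donor,true_recipient True abundances (CFU per g of sample).
#' @param true_rate True conjugation frequency (transconjugants per
#'   recipient), in `[0, 1]`.
#' @param n_mice Number of replicate animals (>= 1).
#' @param cfg A [sim_config()]; `seed` and `mouse_cv` are used.
#' @param day Sampling day label.
#' @param dilution_exponents Integer vector of 10^-k dilutions plated.
#' @param spot_volume_uL Volume per spot (the study spotted 5 uL per dilution
#'   in triplicate).
#' @param n_spots Replicate spots per dilution.
#' @param sample_mass_g Feces mass homogenized per sample.
#' @param homogenate_volume_mL Homogenization volume.
#'
#' @return A spot-assay tibble, one row per spot, with columns `mouse_id`,
#'   `day`, `selection` (`donor`/`recipient`/`transconjugant`),
#'   `dilution_exponent`, `spot_volume_uL`, `colonies`, `sample_mass_g`,
#'   `homogenate_volume_mL`.
#' @export
gen_cfu_assay <- function(true_donor = 1e8, true_recipient = 1e8,
                          true_rate = 1e-4, n_mice = 4L,
                          cfg = sim_config(), day = 1L,
                          dilution_exponents = 0:7, spot_volume_uL = 5,
                          n_spots = 3L, sample_mass_g = 0.1,
                          homogenate_volume_mL = 1) {
  if (n_mice < 1) {
    abort_conjseq("n_mice must be >= 1", "conjseq_bad_input")
  }
  if (true_rate < 0 || true_rate > 1) {
    abort_conjseq("true_rate must lie in [0, 1]", "conjseq_bad_input")
  }
  with_substream(cfg$seed, paste0("cfu_assay_day", day), {
    purrr::map_dfr(seq_len(n_mice), function(m) {
      rec <- 10^stats::rnorm(1, log10(true_recipient), cfg$mouse_cv)
      don <- 10^stats::rnorm(1, log10(true_donor), cfg$mouse_cv)
      conc <- c(donor = don, recipient = rec, transconjugant = rec * true_rate)
      purrr::map_dfr(names(conc), function(sel) {
        grid <- tidyr::expand_grid(dilution_exponent = dilution_exponents,
                                   spot = seq_len(n_spots))
        # expected colonies in one spot of the diluted homogenate
        lam <- conc[[sel]] * sample_mass_g / homogenate_volume_mL *
          (spot_volume_uL / 1000) * 10^(-grid$dilution_exponent)
        tibble(
          mouse_id = sprintf("mouse%02d", m),
          day = day,
          selection = sel,
          dilution_exponent = grid$dilution_exponent,
          spot_volume_uL = spot_volume_uL,
          colonies = stats::rpois(nrow(grid), lam),
          sample_mass_g = sample_mass_g,
          homogenate_volume_mL = homogenate_volume_mL
        )
      })
    })
  })
}
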