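# Conjugation-frequency quantification from serial-dilution spot counts:
# CFU back-calculation, limit-of-detection censoring, fold changes and the
# log-scale correlation/ANOVA summaries used for assay comparisons.

#' Back-calculate CFU from a serial-dilution spot series
#'
#' Replicate spots at each dilution are averaged; the most dilute dilution
#' whose mean colony count lies in the countable band `[1, 100]` is used (if
#' no dilution falls in the band, the most dilute dilution with a non-zero
#' mean is used). CFU concentration in the homogenate is
#' `mean_colonies * 10^dilution_exponent / spot_volume_mL`; when
#' `sample_mass_g` is available the result is rescaled to CFU per gram of
#' sample.
#'
#' @param spots Spot tibble for a single sample and selection: columns
#'   `dilution_exponent`, `spot_volume_uL`, `colonies`, optionally
#'   `sample_mass_g` and `homogenate_volume_mL` (constant within the series).
#' @param homogenate_volume_mL Homogenization volume; only used when the
#'   table lacks a `homogenate_volume_mL` column.
#'
#' @return One-row tibble: `cfu`, `unit` (`"per_g"` or `"per_mL"`),
#'   `below_detection` (all spots zero at every dilution), `dilution_used`,
#'   `mean_colonies`.
#' @export
#' @examples
#' spots <- tibble::tibble(dilution_exponent = 3, spot_volume_uL = 5,
#'                         colonies = c(18, 20, 22))
#' cfu_from_spots(spots)  # 4e6 CFU/mL
cfu_from_spots <- function(spots, homogenate_volume_mL = 1) {
  needed <- c("dilution_exponent", "spot_volume_uL", "colonies")
  if (!all(needed %in% names(spots))) {
    abort_conjseq(paste0("spot table must have columns: ",
                         paste(needed, collapse = ", ")), "conjseq_bad_input")
  }
  if (any(spots$colonies < 0)) {
    abort_conjseq("negative colony counts", "conjseq_bad_input")
  }
  hvol <- if ("homogenate_volume_mL" %in% names(spots)) {
    spots$homogenate_volume_mL[1]
  } else {
    homogenate_volume_mL
  }
  per_dil <- spots %>%
    dplyr::group_by(.data$dilution_exponent, .data$spot_volume_uL) %>%
    dplyr::summarise(mean_colonies = mean(.data$colonies), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$dilution_exponent))

  if (all(per_dil$mean_colonies == 0)) {
    return(tibble(cfu = 0, unit = cfu_unit(spots),
                  below_detection = TRUE,
                  dilution_used = NA_integer_, mean_colonies = 0))
  }
  countable <- dplyr::filter(per_dil, .data$mean_colonies >= 1,
                             .data$mean_colonies <= 100)
  if (nrow(countable) == 0) {
    nonzero <- dplyr::filter(per_dil, .data$mean_colonies > 0)
    if (all(nonzero$mean_colonies > 100)) {
      abort_conjseq("all spots overgrown (> 100 colonies at every dilution)",
                    "conjseq_overgrown")
    }
    countable <- nonzero[1, ]
  }
  row <- countable[1, ]
  conc <- row$mean_colonies * 10^row$dilution_exponent /
    (row$spot_volume_uL / 1000)
  unit <- cfu_unit(spots)
  if (unit == "per_g") {
    conc <- conc * hvol / spots$sample_mass_g[1]
  }
  tibble(cfu = conc, unit = unit, below_detection = FALSE,
         dilution_used = as.integer(row$dilution_exponent),
         mean_colonies = row$mean_colonies)
}

cfu_unit <- function(spots) {
  if ("sample_mass_g" %in% names(spots) && !all(is.na(spots$sample_mass_g))) {
    "per_g"
  } else {
    "per_mL"
  }
}

#' Limit of detection for a conjugation frequency
#'
#' The smallest observable frequency given recipient abundance and the amount
#' of sample actually plated: the frequency at which exactly one
#' transconjugant colony would appear in the largest plated amount of
#' undiluted material. Plating 10x more material lowers the bound 10-fold,
#' which is why caecal samples (more material) detect rarer transfer events
#' than feces.
#'
#' @param recipient Either a spot tibble for the recipient selection (see
#'   [cfu_from_spots()]) or a single recipient CFU value (per g or per mL).
#' @param plated_volume_uL Volume of undiluted homogenate plated.
#' @param homogenate_volume_mL,sample_mass_g Homogenization volume and sample
#'   mass; taken from the spot table when present. For broth assays leave
#'   `sample_mass_g = NA` and the bound is computed per plated mL.
#'
#' @return LOD frequency (transconjugants per recipient).
#' @export
detection_limit <- function(recipient, plated_volume_uL,
                            homogenate_volume_mL = 1, sample_mass_g = NA) {
  if (is.data.frame(recipient)) {
    if ("sample_mass_g" %in% names(recipient)) {
      sample_mass_g <- recipient$sample_mass_g[1]
    }
    if ("homogenate_volume_mL" %in% names(recipient)) {
      homogenate_volume_mL <- recipient$homogenate_volume_mL[1]
    }
    recipient <- cfu_from_spots(recipient, homogenate_volume_mL)$cfu
  }
  if (!is.finite(recipient) || recipient <= 0) {
    abort_conjseq("recipient CFU must be positive to define a detection limit",
                  "conjseq_no_recipient")
  }
  plated_mL <- plated_volume_uL / 1000
  amount <- if (is.na(sample_mass_g)) {
    plated_mL  # broth: CFU per mL times mL plated
  } else {
    sample_mass_g * plated_mL / homogenate_volume_mL  # grams plated
  }
  1 / (recipient * amount)
}

#' Conjugation frequency for one sample, with censoring
#'
#' The frequency is transconjugant CFU divided by recipient CFU. When no
#' transconjugant colony was observed at any dilution the sample is censored:
#' the reported value is the limit-of-detection upper bound for the plated
#' amount, and `censored = TRUE`.
#'
#' @param transconjugant,recipient Spot tibbles for the two selections of the
#'   same sample.
#' @param plated_volume_uL Largest volume of undiluted homogenate plated for
#'   transconjugant detection; defaults to `n_spots * spot_volume_uL` at the
#'   lowest dilution of the transconjugant series.
#' @inheritParams detection_limit
#'
#' @return One-row tibble: `value` (transconjugants per recipient),
#'   `censored`, `recipient_cfu`, `transconjugant_cfu`, `lod`.
#' @export
transfer_rate <- function(transconjugant, recipient, plated_volume_uL = NULL,
                          homogenate_volume_mL = 1) {
  rec <- cfu_from_spots(recipient, homogenate_volume_mL)
  if (rec$below_detection) {
    abort_conjseq("recipient below detection: conjugation frequency undefined",
                  "conjseq_no_recipient")
  }
  tc <- cfu_from_spots(transconjugant, homogenate_volume_mL)
  if (is.null(plated_volume_uL)) {
    lowest <- min(transconjugant$dilution_exponent)
    plated_volume_uL <- sum(
      transconjugant$spot_volume_uL[transconjugant$dilution_exponent == lowest]
    )
  }
  lod <- detection_limit(recipient, plated_volume_uL, homogenate_volume_mL)
  if (tc$below_detection) {
    tibble(value = lod, censored = TRUE,
           recipient_cfu = rec$cfu, transconjugant_cfu = 0, lod = lod)
  } else {
    tibble(value = tc$cfu / rec$cfu, censored = FALSE,
           recipient_cfu = rec$cfu, transconjugant_cfu = tc$cfu, lod = lod)
  }
}

#' Conjugation frequencies for a full spot-assay table
#'
#' Groups a spot-assay tibble (e.g. from [gen_cfu_assay()] or read from CSV)
#' by sample and computes [transfer_rate()] per sample.
#'
#' @param spots Spot tibble with a `selection` column and sample identifier
#'   columns (any of `mouse_id`, `sample_id`, `day` present are used).
#' @inheritParams transfer_rate
#' @return Tibble with one row per sample: identifier columns plus the
#'   [transfer_rate()] columns.
#' @export
transfer_rates <- function(spots, plated_volume_uL = NULL,
                           homogenate_volume_mL = 1) {
  keys <- intersect(c("mouse_id", "sample_id", "plasmid", "day"), names(spots))
  if (!"selection" %in% names(spots)) {
    abort_conjseq("spot table needs a `selection` column", "conjseq_bad_input")
  }
  spots %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(df, key) {
      transfer_rate(
        dplyr::filter(df, .data$selection == "transconjugant"),
        dplyr::filter(df, .data$selection == "recipient"),
        plated_volume_uL = plated_volume_uL,
        homogenate_volume_mL = homogenate_volume_mL
      )
    }) %>%
    dplyr::ungroup()
}

geo_mean <- function(x) exp(mean(log(x)))

#' Fold change between two sets of conjugation frequencies
#'
#' Ratio of the aggregate frequency of set `a` to that of set `b`. The
#' default aggregate is the geometric mean (equivalently, the arithmetic mean
#' on the log scale); `aggregate = "arithmetic"` is provided since published
#' summaries sometimes use plain means. When any constituent rate is a
#' limit-of-detection bound the fold change is flagged as a bound itself.
#'
#' @param a,b [transfer_rate()]-style tibbles (columns `value`, `censored`)
#'   or bare numeric vectors of rates.
#' @param aggregate `"geometric"` or `"arithmetic"`.
#' @return One-row tibble: `fold`, `bound` (TRUE when censoring propagates),
#'   `n_a`, `n_b`.
#' @export
fold_change <- function(a, b, aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  a <- as_rate_tbl(a)
  b <- as_rate_tbl(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort_conjseq("both rate sets must be non-empty", "conjseq_bad_input")
  }
  if (all(b$censored)) {
    abort_conjseq("no uncensored denominator rates: fold change undefined",
                  "conjseq_bad_input")
  }
  agg <- if (aggregate == "geometric") geo_mean else mean
  tibble(
    fold = agg(a$value) / agg(b$value),
    bound = any(a$censored) || any(b$censored),
    n_a = nrow(a), n_b = nrow(b)
  )
}

as_rate_tbl <- function(x) {
  if (is.data.frame(x)) {
    if (!"censored" %in% names(x)) x$censored <- FALSE
    as_tibble(x[, c("value", "censored")])
  } else {
    tibble(value = as.numeric(x), censored = FALSE)
  }
}

#' Squared Pearson correlation of paired log10 conjugation frequencies
#'
#' Used to ask whether transfer measured in one environment predicts transfer
#' in another (e.g. in situ vs agar). Censored pairs are excluded by default;
#' `censored = "substitute"` keeps them at their LOD bound values.
#'
#' @param x,y Paired rate sets ([transfer_rate()]-style tibbles or numeric
#'   vectors), same length and order.
#' @param censored `"exclude"` or `"substitute"`.
#' @return One-row tibble: `r_squared`, `n_used`, `n_excluded`.
#' @export
log_r_squared <- function(x, y, censored = c("exclude", "substitute")) {
  censored <- match.arg(censored)
  x <- as_rate_tbl(x)
  y <- as_rate_tbl(y)
  if (nrow(x) != nrow(y)) {
    abort_conjseq("x and y must be paired (equal length)", "conjseq_bad_input")
  }
  keep <- if (censored == "exclude") !(x$censored | y$censored) else
    rep(TRUE, nrow(x))
  keep <- keep & x$value > 0 & y$value > 0
  if (sum(keep) < 3) {
    abort_conjseq("fewer than 3 usable pairs for correlation",
                  "conjseq_bad_input")
  }
  r <- stats::cor(log10(x$value[keep]), log10(y$value[keep]))
  tibble(r_squared = r^2, n_used = sum(keep), n_excluded = sum(!keep))
}

#' One-way ANOVA on log10-transformed conjugation frequencies
#'
#' Group comparisons of conjugation frequencies are performed on the log
#' scale, where replicate variation is approximately normal.
#'
#' @param rates Numeric vector of positive rates, or a named list of numeric
#'   vectors (one per group, `groups` then ignored).
#' @param groups Group labels aligned with `rates`.
#' @return Object of class `conjseq_anova`: one-row tibble with `f`, `p`,
#'   `df_between`, `df_within`, `n`, carrying the fitted [stats::aov] model
#'   as attribute `fit`.
#' @export
anova_log <- function(rates, groups = NULL) {
  if (is.list(rates) && !is.data.frame(rates)) {
    groups <- rep(names(rates) %||% seq_along(rates), lengths(rates))
    rates <- unlist(rates, use.names = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort_conjseq(
      "all rates must be positive for log-scale ANOVA (handle censored values first)",
      "conjseq_bad_input"
    )
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    abort_conjseq("need >= 2 groups with >= 2 observations each",
                  "conjseq_bad_input")
  }
  fit <- stats::aov(log10(rates) ~ groups)
  s <- summary(fit)[[1]]
  out <- tibble(
    f = s[["F value"]][1], p = s[["Pr(>F)"]][1],
    df_between = s[["Df"]][1], df_within = s[["Df"]][2],
    n = length(rates)
  )
  attr(out, "fit") <- fit
  class(out) <- c("conjseq_anova", class(out))
  out
}

#' @export
tidy.conjseq_anova <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x))[, c("f", "p", "df_between",
                                                  "df_within", "n")])
}

#' @export
glance.conjseq_anova <- function(x, ...) tidy(x)

#' Per-group summary of log10 conjugation frequencies
#'
#' @param rates Rate tibble (columns `value`, optionally `censored`) or
#'   numeric vector.
#' @param groups Group labels.
#' @param censored `"exclude"` (default) or `"substitute"` LOD bounds.
#' @return Tibble per group: `n`, `mean_log10`, `sd_log10`, `min_log10`,
#'   `max_log10`, `geo_mean_rate`.
#' @export
rate_summary <- function(rates, groups, censored = c("exclude", "substitute")) {
  censored <- match.arg(censored)
  r <- as_rate_tbl(rates)
  r$group <- groups
  if (censored == "exclude") r <- dplyr::filter(r, !.data$censored)
  r %>%
    dplyr::filter(.data$value > 0) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n = dplyr::n(),
      mean_log10 = mean(log10(.data$value)),
      sd_log10 = stats::sd(log10(.data$value)),
      min_log10 = min(log10(.data$value)),
      max_log10 = max(log10(.data$value)),
      geo_mean_rate = geo_mean(.data$value),
      .groups = "drop"
    )
}

#' Plot conjugation frequencies per group on a log scale
#'
#' @param rates Rate tibble or numeric vector (see [rate_summary()]).
#' @param groups Group labels.
#' @return A ggplot object: points per sample (open circles for censored
#'   LOD bounds) with the group geometric mean marked.
#' @export
plot_transfer_rates <- function(rates, groups) {
  r <- as_rate_tbl(rates)
  r$group <- groups
  means <- rate_summary(r, r$group, censored = "exclude")
  ggplot2::ggplot(r, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(ggplot2::aes(shape = .data$censored),
                         width = 0.15, height = 0, size = 2) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(x = .data$group, y = .data$geo_mean_rate),
                        inherit.aes = FALSE, shape = 95, size = 10) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "censored (LOD)") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "transconjugants per recipient") +
    ggplot2::theme_minimal()
}
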