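# Larval photophysiology and symbiont density from raw measurements.

#' Fit an oxygen flux rate from a chamber time series
#'
#' Regresses oxygen amount against time over the measurement window for the
#' larval chamber and its matched blank, and reports the blank-corrected
#' slope per larva: `rate = (slope_sample - slope_blank) / n_larvae`, in
#' nmol O2 per larva per minute. Dark-phase rates are returned with the sign
#' flipped, so respiration is a positive consumption magnitude and the gross
#' photosynthesis identity `P_G = P_N + R_D` is additive.
#'
#' Only slopes enter the rate, so the result is invariant to adding a
#' constant to all oxygen readings.
#'
#' @param series Data frame with columns `time_min`, `o2_nmol` and logical
#'   `is_blank`; both the sample and blank series need at least 3 readings.
#' @param n_larvae Number of larvae in the chamber (> 0).
#' @param phase `"light"` (net photosynthesis, P_N) or `"dark"` (dark
#'   respiration, R_D).
#' @return Rate in nmol O2 larva^-1 min^-1.
#' @export
fit_rate <- function(series, n_larvae, phase = c("light", "dark")) {
  phase <- match.arg(phase)
  if (n_larvae <= 0) ho_stop("n_larvae must be > 0", "holonet_input_error")
  need <- c("time_min", "o2_nmol", "is_blank")
  if (!all(need %in% names(series))) {
    ho_stop(sprintf("series needs columns: %s", paste(need, collapse = ", ")),
            "holonet_input_error")
  }
  smp <- series[!series$is_blank, , drop = FALSE]
  blk <- series[series$is_blank, , drop = FALSE]
  if (nrow(smp) < 3 || nrow(blk) < 3) {
    ho_stop("need >= 3 readings in both the sample and blank series",
            "holonet_insufficient_data")
  }
  slope <- function(d) {
    if (is.unsorted(d$time_min, strictly = TRUE)) {
      ho_stop("reading times must be strictly increasing", "holonet_input_error")
    }
    unname(stats::coef(stats::lm(o2_nmol ~ time_min, data = d))[2])
  }
  net <- (slope(smp) - slope(blk)) / n_larvae
  if (phase == "dark") -net else net
}

#' Gross photosynthesis
#'
#' `P_G = P_N + R_D`, with `R_D` the positive respiration magnitude returned
#' by [fit_rate()] for the dark phase; hence `P_G >= P_N` whenever
#' `R_D >= 0`.
#'
#' @param p_n Net photosynthesis rate(s).
#' @param r_d Dark respiration magnitude(s), same samples.
#' @return Gross photosynthesis, same units.
#' @export
gross_photosynthesis <- function(p_n, r_d) {
  p_n + r_d
}

#' Symbiont cell density per larva
#'
#' Larvae are homogenised and resuspended in a fixed homogenate volume; an
#' aliquot is counted on a haemocytometer. Density scales back from the
#' counted concentration: `density = aliquot_concentration *
#' homogenate_volume / n_larvae` (cells per larva).
#'
#' @param aliquot_concentration Cells per uL counted in the aliquot.
#' @param homogenate_volume Total homogenate volume in uL (default 200 uL of
#'   filtered seawater).
#' @param n_larvae Number of larvae homogenised (> 0).
#' @return Cells per larva.
#' @export
symbiont_density <- function(aliquot_concentration, homogenate_volume = 200,
                             n_larvae = 20) {
  if (any(n_larvae <= 0)) ho_stop("n_larvae must be > 0", "holonet_input_error")
  if (any(aliquot_concentration < 0) || any(homogenate_volume <= 0)) {
    ho_stop("concentration must be >= 0 and volume > 0", "holonet_input_error")
  }
  aliquot_concentration * homogenate_volume / n_larvae
}

#' One-way ANOVA of a physiology value, one treatment vs control
#'
#' Standard one-way F-test between the named treatment group and the control
#' group.
#'
#' @param values Named numeric vector (names = sample ids) or a vector
#'   aligned with `design` rows.
#' @param design Sample design.
#' @param treatment Nitrate level to test against the control.
#' @return Tibble: `comparison`, `f_value`, `p_value`, `df1`, `df2`.
#' @export
anova_by_treatment <- function(values, design, treatment) {
  check_design(design)
  if (!is.null(names(values))) values <- values[design$sample_id]
  keep <- design$is_control | design$treatment == treatment
  if (!any(design$treatment == treatment & !design$is_control)) {
    ho_stop(sprintf("treatment %s not present in design", treatment),
            "holonet_design_error")
  }
  v <- values[keep]
  g <- factor(ifelse(design$is_control[keep], "control", "treatment"))
  if (any(table(g) < 2)) {
    ho_stop("each group needs >= 2 values", "holonet_design_error")
  }
  a <- stats::anova(stats::aov(v ~ g))
  tibble::tibble(
    comparison = sprintf("control-%g", treatment),
    f_value = a$`F value`[1],
    p_value = a$`Pr(>F)`[1],
    df1 = a$Df[1],
    df2 = a$Df[2]
  )
}
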