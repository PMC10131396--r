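# Synthetic tri-compartment data generator.
#
# Emulates a nitrate-enrichment larval experiment: five nitrate levels
# (ambient control plus four enrichments) with replicate aquaria,
# negative-binomial transcript counts per holobiont compartment with planted
# differential expression and cross-compartment correlation structure, and
# symbiont physiology driven linearly by named transcripts with an
# aquarium-batch random intercept.

#' Generate the sample design of a nitrate-enrichment experiment
#'
#' Builds a balanced design of five nitrate treatments (an ambient control of
#' 2.5 uM plus 5, 10, 20 and 40 uM enrichments by default) with `n_reps`
#' replicate aquaria per treatment.
#'
#' @param n_reps Number of replicate aquaria per treatment (>= 2; downstream
#'   two-group tests need replication).
#' @param treatments Numeric nitrate levels in uM; the first is the control.
#' @param seed Unused (the design is deterministic); kept so that all
#'   generator functions share a signature.
#'
#' @return A tibble with columns `sample_id`, `treatment` (uM),
#'   `replicate` (aquarium index within treatment) and `is_control`.
#' @examples
#' generate_design(n_reps = 4)
#' @export
generate_design <- function(n_reps = 4,
                            treatments = c(2.5, 5, 10, 20, 40),
                            seed = NULL) {
  if (n_reps < 2) {
    ho_stop("n_reps must be >= 2: downstream tests need replication",
            "holonet_design_error")
  }
  control <- treatments[1]
  design <- tibble::tibble(
    treatment = rep(treatments, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(treatments))
  )
  design$is_control <- design$treatment == control
  design$sample_id <- ifelse(
    design$is_control,
    sprintf("ctrl_r%d", design$replicate),
    sprintf("n%g_r%d", design$treatment, design$replicate)
  )
  design[, c("sample_id", "treatment", "replicate", "is_control")]
}

#' Transcript identifiers used by the generator
#' @noRd
transcript_ids <- function(compartment, n) {
  sprintf("%s_t%04d", compartment, seq_len(n))
}

#' Generate tri-compartment negative-binomial count matrices
#'
#' Simulates raw RNA-seq counts for the three holobiont compartments with
#' known planted structure: a fraction of transcripts per compartment is
#' differentially expressed (log2 mean shift in every enriched treatment
#' relative to control), and designated cross-compartment transcript pairs
#' share a per-sample Gaussian latent factor on the log2-mean scale, which
#' induces a controllable Spearman correlation.
#'
#' Counts are negative binomial with constant dispersion; per-sample library
#' size factors are log-normal around `lib_size`.
#'
#' @param design Sample design from [generate_design()].
#' @param n_transcripts Named integer vector of transcripts per compartment
#'   (each >= 50). Names are the compartment labels.
#' @param de_fraction Fraction of transcripts planted as differentially
#'   expressed (applied per compartment).
#' @param effect_size_log2 Absolute planted log2 fold change (must exceed 1
#'   so planted transcripts are discoverable under a `|logFC| > 1` rule);
#'   sign is randomised per transcript.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   must be > 0.
#' @param corr_block_spec Optional data frame describing planted
#'   cross-compartment pairs with columns `compartment_a`, `transcript_a`,
#'   `compartment_b`, `transcript_b` and optionally `loading_a`, `loading_b`
#'   (defaults 1). Each row gets its own shared latent factor.
#' @param lib_size Central library size (total expected counts per sample).
#' @param lib_size_cv_log SD of the log-normal library size factor.
#' @param latent_sd SD of the shared latent factors (log2-mean scale).
#' @param base_log2_mean,base_log2_sd Mean/SD of the baseline log2 relative
#'   expression drawn per transcript.
#' @param sampling `"nb"` for negative-binomial sampling (default) or
#'   `"mean"` to return the rounded expected counts (a noise-free limit
#'   useful for validating the planted structure).
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   matrices bit for bit.
#'
#' @return A list with elements `counts` (named list of transcript x sample
#'   integer matrices), and `ground_truth`, a list with `de_transcripts`
#'   (tibble: compartment, transcript_id, comparison, true_lfc),
#'   `correlated_pairs` (tibble with loadings and implied sign),
#'   `physio_drivers` (empty tibble, filled by [generate_physiology()]) and
#'   `seed`.
#' @export
generate_counts <- function(design,
                            n_transcripts = c(coral = 300, symbiodiniaceae = 120,
                                              prokaryote = 50),
                            de_fraction = 0.1,
                            effect_size_log2 = 2,
                            dispersion = 0.01,
                            corr_block_spec = NULL,
                            lib_size = 3e5,
                            lib_size_cv_log = 0.1,
                            latent_sd = 1,
                            base_log2_mean = 5,
                            base_log2_sd = 1.5,
                            sampling = c("nb", "mean"),
                            seed = 1) {
  check_design(design)
  sampling <- match.arg(sampling)
  if (any(n_transcripts < 50)) {
    ho_stop("each compartment needs >= 50 transcripts", "holonet_input_error")
  }
  if (dispersion <= 0) ho_stop("dispersion must be > 0", "holonet_input_error")
  if (de_fraction > 0 && abs(effect_size_log2) <= 1) {
    ho_stop("|effect_size_log2| must exceed 1 so planted transcripts pass a |logFC| > 1 rule",
            "holonet_input_error")
  }
  compartments <- names(n_transcripts)
  if (is.null(compartments)) {
    ho_stop("n_transcripts must be a named vector", "holonet_input_error")
  }

  set.seed(seed)
  n_samp <- nrow(design)
  treatments <- sort(unique(design$treatment[!design$is_control]))
  comparisons <- sprintf("control-%g", treatments)

  ids <- lapply(compartments, function(cc) transcript_ids(cc, n_transcripts[[cc]]))
  names(ids) <- compartments

  # validate the correlation block spec before drawing anything else
  if (!is.null(corr_block_spec) && nrow(corr_block_spec) > 0) {
    cbs <- as.data.frame(corr_block_spec)
    need <- c("compartment_a", "transcript_a", "compartment_b", "transcript_b")
    if (!all(need %in% names(cbs))) {
      ho_stop(sprintf("corr_block_spec needs columns: %s", paste(need, collapse = ", ")),
              "holonet_spec_error")
    }
    if (is.null(cbs$loading_a)) cbs$loading_a <- 1
    if (is.null(cbs$loading_b)) cbs$loading_b <- 1
    for (k in seq_len(nrow(cbs))) {
      for (side in c("a", "b")) {
        cc <- cbs[[paste0("compartment_", side)]][k]
        tt <- cbs[[paste0("transcript_", side)]][k]
        if (!cc %in% compartments || !tt %in% ids[[cc]]) {
          ho_stop(sprintf("corr_block_spec references unknown transcript '%s' in compartment '%s'",
                          tt, cc), "holonet_spec_error")
        }
      }
    }
  } else {
    cbs <- NULL
  }

  # per-sample library size factors (shared across compartments, as all
  # compartments are sequenced from the same library)
  lib_factor <- exp(stats::rnorm(n_samp, 0, lib_size_cv_log))

  # latent factors for correlated pairs: one per block row, per sample
  n_blocks <- if (is.null(cbs)) 0L else nrow(cbs)
  latent <- if (n_blocks > 0) {
    matrix(stats::rnorm(n_blocks * n_samp, 0, latent_sd), n_blocks, n_samp)
  } else NULL

  de_rows <- list()
  counts <- list()
  for (cc in compartments) {
    n_t <- n_transcripts[[cc]]
    base <- stats::rnorm(n_t, base_log2_mean, base_log2_sd)
    log2mu <- matrix(base, n_t, n_samp)
    rownames(log2mu) <- ids[[cc]]

    n_de <- round(de_fraction * n_t)
    if (n_de > 0) {
      de_idx <- sample.int(n_t, n_de)
      de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
      trt_cols <- which(!design$is_control)
      for (k in seq_len(n_de)) {
        log2mu[de_idx[k], trt_cols] <- log2mu[de_idx[k], trt_cols] +
          de_sign[k] * abs(effect_size_log2)
      }
      de_rows[[cc]] <- tibble::tibble(
        compartment = cc,
        transcript_id = rep(ids[[cc]][de_idx], each = length(comparisons)),
        comparison = rep(comparisons, times = n_de),
        true_lfc = rep(de_sign * abs(effect_size_log2), each = length(comparisons))
      )
    }

    if (n_blocks > 0) {
      for (k in seq_len(n_blocks)) {
        if (cbs$compartment_a[k] == cc) {
          log2mu[cbs$transcript_a[k], ] <- log2mu[cbs$transcript_a[k], ] +
            cbs$loading_a[k] * latent[k, ]
        }
        if (cbs$compartment_b[k] == cc) {
          log2mu[cbs$transcript_b[k], ] <- log2mu[cbs$transcript_b[k], ] +
            cbs$loading_b[k] * latent[k, ]
        }
      }
    }

    mu <- 2^log2mu
    # scale so the expected column total tracks the library size
    mu <- mu * (lib_size / mean(colSums(mu)))
    mu <- sweep(mu, 2, lib_factor, `*`)

    cnt <- if (sampling == "nb") {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow(mu), ncol(mu))
    } else {
      round(mu)
    }
    dimnames(cnt) <- list(ids[[cc]], design$sample_id)
    counts[[cc]] <- cnt
  }

  ground_truth <- list(
    de_transcripts = if (length(de_rows)) dplyr::bind_rows(de_rows) else
      tibble::tibble(compartment = character(), transcript_id = character(),
                     comparison = character(), true_lfc = numeric()),
    correlated_pairs = if (!is.null(cbs)) {
      tibble::as_tibble(cbs)[, c("compartment_a", "transcript_a",
                                 "compartment_b", "transcript_b",
                                 "loading_a", "loading_b")] |>
        dplyr::mutate(sign = ifelse(.data$loading_a * .data$loading_b >= 0,
                                    "positive", "negative"))
    } else {
      tibble::tibble(compartment_a = character(), transcript_a = character(),
                     compartment_b = character(), transcript_b = character(),
                     loading_a = numeric(), loading_b = numeric(),
                     sign = character())
    },
    physio_drivers = tibble::tibble(response = character(),
                                    compartment = character(),
                                    transcript_id = character(),
                                    beta = numeric()),
    seed = seed
  )
  list(counts = counts, ground_truth = ground_truth)
}

#' Build a physiology driver specification from generated expression
#'
#' Convenience constructor: picks coefficients for named transcripts so each
#' planted driver contributes a response component with a target standard
#' deviation (in response units), i.e. `beta = target_sd / sd(CPM)`.
#'
#' @param cpm_list Named list of CPM matrices (one per compartment).
#' @param response One of `"density"`, `"photosynthesis"`, `"respiration"`.
#' @param compartment Compartment the driver transcripts belong to.
#' @param transcript_ids Character vector of driver transcripts.
#' @param target_sd Standard deviation of each driver's contribution, in
#'   response units; sign is taken from `signs`.
#' @param signs Optional vector of +1/-1 per transcript (default +1).
#' @return A tibble usable as `driver_spec` in [generate_physiology()].
#' @export
make_driver_spec <- function(cpm_list, response, compartment, transcript_ids,
                             target_sd, signs = NULL) {
  if (!compartment %in% names(cpm_list)) {
    ho_stop(sprintf("unknown compartment '%s'", compartment), "holonet_spec_error")
  }
  mat <- cpm_list[[compartment]]
  missing <- setdiff(transcript_ids, rownames(mat))
  if (length(missing)) {
    ho_stop(sprintf("driver transcripts not in matrix: %s",
                    paste(missing, collapse = ", ")), "holonet_spec_error")
  }
  signs <- signs %||% rep(1, length(transcript_ids))
  sds <- apply(mat[transcript_ids, , drop = FALSE], 1, stats::sd)
  sds[sds == 0] <- 1
  tibble::tibble(
    response = response,
    compartment = compartment,
    transcript_id = transcript_ids,
    beta = signs * target_sd / sds
  )
}

#' Default planted-driver configuration
#'
#' The generator's standard planted-driver setting: one dominant driver
#' transcript per physiology response, drawn at random from the named
#' compartment, with a contribution of `effect_multiple` times the residual
#' noise SD (so the default multiple of 3 gives a clearly detectable,
#' physiologically dominant transcript, the regime the selection procedure
#' targets).
#'
#' @param cpm_list Named list of CPM matrices.
#' @param seed Integer seed for the random driver draw.
#' @param compartment Compartment to draw the drivers from.
#' @param effect_multiple Driver component SD as a multiple of the residual
#'   noise SD (`noise_sd` in [generate_physiology()], default 0.03 of the
#'   response baseline).
#' @param noise_sd,bases Residual-noise fraction and response baselines used
#'   to translate the multiple into response units; keep in step with the
#'   [generate_physiology()] arguments.
#' @return Driver tibble usable as `driver_spec` in [generate_physiology()].
#' @export
default_driver_spec <- function(cpm_list, seed = 1, compartment = "coral",
                                effect_multiple = 3, noise_sd = 0.03,
                                bases = c(density = 1.75e4,
                                          photosynthesis = 0.8,
                                          respiration = 0.5)) {
  set.seed(seed)
  drv <- sample(rownames(cpm_list[[compartment]]), length(bases))
  dplyr::bind_rows(lapply(seq_along(bases), function(i) {
    make_driver_spec(cpm_list, names(bases)[i], compartment, drv[i],
                     target_sd = effect_multiple * noise_sd * bases[[i]])
  }))
}

#' Generate symbiont physiology and oxygen time series
#'
#' Each sample's Symbiodiniaceae density, net photosynthesis (`p_n`) and dark
#' respiration (`r_d`) are linear functions of named driver transcript CPMs,
#' plus an aquarium-batch random intercept shared by samples with the same
#' replicate index (emulating measurement runs processed together) and
#' residual noise. Oxygen series are straight lines over a 10-minute window
#' whose slopes encode `p_n` (light) and `r_d` (dark) for a chamber of
#' `n_larvae` larvae, plus matched blank-chamber series.
#'
#' `random_effect_sd` and `noise_sd` are relative to each response's
#' baseline, so one value serves responses on very different scales
#' (density ~ 1.75e4 cells/larva; rates ~ 1 nmol O2/larva/min). The default
#' density baseline keeps simulated densities within the 1.6e4-1.9e4
#' cells-per-larva range typical of Pocillopora damicornis larvae.
#'
#' @param design Sample design from [generate_design()].
#' @param cpm_list Named list of CPM matrices; driver transcripts are looked
#'   up here.
#' @param driver_spec Tibble with columns `response`, `compartment`,
#'   `transcript_id`, `beta` (see [make_driver_spec()]); `NULL` for no
#'   drivers.
#' @param random_effect_sd SD of the aquarium-batch random intercept,
#'   relative to the response baseline.
#' @param noise_sd Residual SD, relative to the response baseline.
#' @param seed Integer seed.
#' @param density_base,pn_base,rd_base Baseline (intercept) of each response:
#'   cells per larva and nmol O2 per larva per minute.
#' @param n_larvae Larvae per respirometry chamber.
#' @param blank_slope Slope of the blank chamber series (nmol O2/min),
#'   emulating sensor drift / microbial background.
#' @param o2_noise_sd SD of oxygen reading noise (nmol).
#' @param window_min Measurement window length in minutes.
#' @param readings_per_min Oxygen readings per minute.
#'
#' @return A list: `physiology` (tibble sample_id, density, p_n, r_d),
#'   `oxygen` (long tibble sample_id, phase, time_min, o2_nmol, is_blank,
#'   n_larvae) and `physio_drivers` (the driver tibble, for merging into a
#'   ground-truth record).
#' @export
generate_physiology <- function(design,
                                cpm_list,
                                driver_spec = NULL,
                                random_effect_sd = 0.05,
                                noise_sd = 0.03,
                                seed = 1,
                                density_base = 1.75e4,
                                pn_base = 0.8,
                                rd_base = 0.5,
                                n_larvae = 20,
                                blank_slope = 0.5,
                                o2_noise_sd = 1,
                                window_min = 10,
                                readings_per_min = 1) {
  check_design(design)
  set.seed(seed)
  n <- nrow(design)
  bases <- c(density = density_base, photosynthesis = pn_base,
             respiration = rd_base)

  if (!is.null(driver_spec) && nrow(driver_spec) > 0) {
    for (k in seq_len(nrow(driver_spec))) {
      cc <- driver_spec$compartment[k]
      tt <- driver_spec$transcript_id[k]
      if (!cc %in% names(cpm_list) || !tt %in% rownames(cpm_list[[cc]])) {
        ho_stop(sprintf("driver transcript '%s' not found in compartment '%s'", tt, cc),
                "holonet_spec_error")
      }
      if (!driver_spec$response[k] %in% names(bases)) {
        ho_stop(sprintf("unknown response '%s'", driver_spec$response[k]),
                "holonet_spec_error")
      }
    }
  }

  # one random intercept per replicate batch, per response
  batches <- sort(unique(design$replicate))
  vals <- matrix(0, n, 3, dimnames = list(design$sample_id, names(bases)))
  for (r in names(bases)) {
    u <- stats::rnorm(length(batches), 0, random_effect_sd * bases[[r]])
    names(u) <- as.character(batches)
    eps <- stats::rnorm(n, 0, noise_sd * bases[[r]])
    v <- rep(bases[[r]], n) + u[as.character(design$replicate)] + eps
    if (!is.null(driver_spec) && nrow(driver_spec) > 0) {
      dk <- driver_spec[driver_spec$response == r, , drop = FALSE]
      for (k in seq_len(nrow(dk))) {
        x <- cpm_list[[dk$compartment[k]]][dk$transcript_id[k], design$sample_id]
        # centred so the baseline stays at the response's nominal level; the
        # realised intercept absorbs -beta * mean(CPM)
        v <- v + dk$beta[k] * (x - mean(x))
      }
    }
    vals[, r] <- v
  }
  vals[, "density"] <- pmax(vals[, "density"], 0)

  physiology <- tibble::tibble(
    sample_id = design$sample_id,
    density = unname(vals[, "density"]),
    p_n = unname(vals[, "photosynthesis"]),
    r_d = unname(vals[, "respiration"])
  )

  # oxygen series: light slope = p_n * n_larvae + blank drift; dark slope =
  # -r_d * n_larvae + blank drift; blanks carry the drift alone
  times <- seq(0, window_min, by = 1 / readings_per_min)
  o2_start <- 500
  rows <- vector("list", n * 4L)
  i <- 1L
  for (s in seq_len(n)) {
    for (ph in c("light", "dark")) {
      slope <- if (ph == "light") physiology$p_n[s] * n_larvae + blank_slope else
        -physiology$r_d[s] * n_larvae + blank_slope
      for (blk in c(FALSE, TRUE)) {
        sl <- if (blk) blank_slope else slope
        rows[[i]] <- tibble::tibble(
          sample_id = design$sample_id[s],
          phase = ph,
          time_min = times,
          o2_nmol = o2_start + sl * times + stats::rnorm(length(times), 0, o2_noise_sd),
          is_blank = blk,
          n_larvae = n_larvae
        )
        i <- i + 1L
      }
    }
  }
  oxygen <- dplyr::bind_rows(rows)

  drivers <- if (is.null(driver_spec)) {
    tibble::tibble(response = character(), compartment = character(),
                   transcript_id = character(), beta = numeric())
  } else tibble::as_tibble(driver_spec)

  list(physiology = physiology, oxygen = oxygen, physio_drivers = drivers)
}
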