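# Readers and writers for the pipeline's tabular formats, plus the
# end-to-end pipeline orchestrator. All tables are UTF-8 with a mandatory
# header row; expression matrices are TSV with transcript ids in the first
# column, designs and physiology are CSV, symbiosis parameters are YAML or
# JSON keyed by the model's symbol names.

check_readable <- function(path) {
  if (!file.exists(path)) {
    ho_stop(sprintf("file not found: %s", path), "holonet_io_error")
  }
  if (file.size(path) == 0) {
    ho_stop(sprintf("empty input file: %s", path), "holonet_io_error")
  }
  invisible(path)
}

#' Write / read an expression matrix as TSV
#'
#' Rows are transcripts, columns samples; the first column holds transcript
#' ids. Reading validates uniqueness of ids and numeric cells.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return `read_counts_tsv` returns the matrix; `write_counts_tsv` returns
#'   `path` invisibly.
#' @export
write_counts_tsv <- function(mat, path) {
  check_expression_matrix(mat, "mat")
  df <- data.frame(transcript_id = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  check_readable(path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"transcript_id" %in% names(df)) {
    ho_stop(sprintf("%s: missing 'transcript_id' column", path), "holonet_io_error")
  }
  ids <- df$transcript_id
  if (anyDuplicated(ids)) {
    ho_stop(sprintf("%s: duplicate transcript id '%s'", path,
                    ids[duplicated(ids)][1]), "holonet_io_error")
  }
  vals <- as.data.frame(df[, setdiff(names(df), "transcript_id"), drop = FALSE])
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    ho_stop(sprintf("%s: non-numeric column(s): %s", path,
                    paste(bad, collapse = ", ")), "holonet_io_error")
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write / read a sample design as CSV
#' @param design Design tibble (see [generate_design()]).
#' @param path File path.
#' @return The design tibble (read) or `path` invisibly (write).
#' @export
write_design_csv <- function(design, path) {
  check_design(design)
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  check_readable(path)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_design(d)
  d
}

#' Write / read a physiology summary as CSV
#' @param physiology Tibble with `sample_id` and numeric response columns.
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_physiology_csv <- function(physiology, path) {
  readr::write_csv(physiology, path)
  invisible(path)
}

#' @rdname write_physiology_csv
#' @export
read_physiology_csv <- function(path) {
  check_readable(path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a network edge list for Cytoscape import
#'
#' Tab-separated with columns source, target, rho, p_value, sign,
#' network_name.
#'
#' @param network A `bipartite_network`.
#' @param path File path.
#' @return `path` invisibly.
#' @export
write_edges_tsv <- function(network, path) {
  e <- network$edges
  out <- tibble::tibble(source = e$transcript_a, target = e$transcript_b,
                        rho = e$rho, p_value = e$p_value, sign = e$sign,
                        network_name = network$name)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write node attributes (compartment, centrality, core flag) as TSV
#'
#' @param network A `bipartite_network`.
#' @param path File path.
#' @param k Core set size for the `is_core` flag.
#' @return `path` invisibly.
#' @export
write_nodes_tsv <- function(network, path, k = 20) {
  ab <- adjusted_betweenness(network)
  core <- if (nrow(ab)) core_transcripts(network, k)$transcript_id else character()
  ab$is_core <- ab$transcript_id %in% core
  readr::write_tsv(ab, path)
  invisible(path)
}

#' Write / read symbiosis model parameters (YAML or JSON by extension)
#'
#' @param params A `symbiosis_params` object.
#' @param path Path ending in `.yaml`/`.yml` or `.json`.
#' @return The params object (read) or `path` invisibly (write).
#' @export
write_symbiosis_params <- function(params, path) {
  vals <- unclass(params)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @rdname write_symbiosis_params
#' @export
read_symbiosis_params <- function(path) {
  check_readable(path)
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  do.call(symbiosis_params, vals)
}

#' Write / read a model trajectory as CSV (t, H, S, B)
#' @param traj Tibble from [simulate_symbiosis()].
#' @param path File path.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(traj, path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  check_readable(path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Pipeline configuration
#'
#' Collects stage parameters with defaults matching the analysis's stated
#' constants: |logFC| > 1; p thresholds 1e-4 (coral, Symbiodiniaceae) and
#' 1e-3 (prokaryote); network edge filter alpha = 0.05; 20 core transcripts;
#' selection in blocks of 10 over 100 runs with retention thresholds of 95
#' (coral) and 70 (prokaryote).
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @param n_reps Replicate aquaria per treatment (synthetic design).
#' @param n_transcripts Named transcripts-per-compartment vector.
#' @param de_fraction,effect_size_log2,dispersion Count simulator settings.
#' @param lfc_threshold,p_thresholds DET thresholds (named per compartment).
#' @param alpha Network edge significance level.
#' @param k_core Core transcripts per network.
#' @param n_runs,n_per_fit,threshold_runs Selection procedure settings
#'   (`threshold_runs` named per predictor compartment).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("holonet_run_"),
                            seed = 1,
                            n_reps = 4,
                            n_transcripts = c(coral = 300,
                                              symbiodiniaceae = 120,
                                              prokaryote = 50),
                            de_fraction = 0.1,
                            effect_size_log2 = 2,
                            dispersion = 0.01,
                            lfc_threshold = 1,
                            p_thresholds = c(coral = 1e-4,
                                             symbiodiniaceae = 1e-4,
                                             prokaryote = 1e-3),
                            alpha = 0.05,
                            k_core = 20,
                            n_runs = 100,
                            n_per_fit = 10,
                            threshold_runs = c(coral = 95, prokaryote = 70)) {
  cfg <- list(out_dir = out_dir, seed = seed, n_reps = n_reps,
              n_transcripts = n_transcripts, de_fraction = de_fraction,
              effect_size_log2 = effect_size_log2, dispersion = dispersion,
              lfc_threshold = lfc_threshold, p_thresholds = p_thresholds,
              alpha = alpha, k_core = k_core, n_runs = n_runs,
              n_per_fit = n_per_fit, threshold_runs = threshold_runs)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate-data, differential expression / DET calling, the three
#' cross-compartment networks with centrality and core transcripts, and the
#' physiology selection procedure for coral and prokaryotic predictors,
#' writing every stage's tables plus a machine-readable run manifest
#' (package version, seed, config digest, output files) under
#' `config$out_dir`. Stages draw their randomness from child seeds derived
#' from the global seed, so reruns are byte-reproducible.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    ho_stop("config must come from pipeline_config()", "holonet_config_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    outs <<- c(outs, path)
  }

  message("stage: simulate-data")
  design <- generate_design(config$n_reps)
  sim <- generate_counts(design, config$n_transcripts,
                         de_fraction = config$de_fraction,
                         effect_size_log2 = config$effect_size_log2,
                         dispersion = config$dispersion,
                         seed = stage_seed(config$seed, 1))
  cpms <- lapply(sim$counts, cpm)
  phys <- generate_physiology(design, cpms, seed = stage_seed(config$seed, 2))
  emit(write_design_csv, design, "design.csv")
  for (cc in names(sim$counts)) {
    emit(write_counts_tsv, sim$counts[[cc]], sprintf("counts_%s.tsv", cc))
    emit(write_counts_tsv, cpms[[cc]], sprintf("cpm_%s.tsv", cc))
  }
  emit(write_physiology_csv, phys$physiology, "physiology.csv")
  emit(function(obj, path) readr::write_csv(obj, path), phys$oxygen, "oxygen.csv")
  emit(function(obj, path) jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                                digits = NA, na = "null"),
       sim$ground_truth, "ground_truth.json")

  message("stage: de")
  treatments <- sort(unique(design$treatment[!design$is_control]))
  dets <- list()
  for (cc in names(cpms)) {
    de <- dplyr::bind_rows(lapply(treatments, function(tr) {
      pairwise_de(cpms[[cc]], design, tr,
                  lfc_threshold = config$lfc_threshold,
                  p_threshold = config$p_thresholds[[cc]])
    }))
    emit(function(obj, path) readr::write_tsv(obj, path), de,
         sprintf("de_%s.tsv", cc))
    dets[[cc]] <- call_dets(de, cc, p_threshold = config$p_thresholds[[cc]],
                            lfc_threshold = config$lfc_threshold)
    emit(function(obj, path) jsonlite::write_json(
      as.list(obj$venn_counts), path, auto_unbox = TRUE),
      dets[[cc]], sprintf("venn_%s.json", cc))
  }

  message("stage: network")
  pairs_of <- list(c("coral", "symbiodiniaceae"),
                   c("symbiodiniaceae", "prokaryote"),
                   c("coral", "prokaryote"))
  networks <- list()
  for (pp in pairs_of) {
    a <- dets[[pp[1]]]$union; b <- dets[[pp[2]]]$union
    if (length(a) == 0 || length(b) == 0) next
    cp <- correlate_pairs(cpms[[pp[1]]][a, , drop = FALSE],
                          cpms[[pp[2]]][b, , drop = FALSE],
                          compartment_a = pp[1], compartment_b = pp[2])
    net <- build_network(cp, alpha = config$alpha)
    networks[[net$name]] <- net
    emit(write_edges_tsv, net, sprintf("edges_%s.tsv", net$name))
    emit(function(obj, path) write_nodes_tsv(obj, path, k = config$k_core),
         net, sprintf("nodes_%s.tsv", net$name))
  }

  message("stage: select")
  sel_tables <- list()
  sel_idx <- 3L
  for (cc in c("coral", "prokaryote")) {
    preds <- cpms[[cc]]
    for (resp in c("density", "p_n", "r_d")) {
      sr <- repeated_selection(
        phys$physiology[[resp]], preds, design$replicate,
        n_per_fit = config$n_per_fit, n_runs = config$n_runs,
        threshold_runs = config$threshold_runs[[cc]],
        seed = stage_seed(config$seed, sel_idx),
        response_name = sprintf("%s~%s", resp, cc))
      sel_idx <- sel_idx + 1L
      sel_tables[[sr$response]] <- sr
    }
  }
  sel_summary <- summarize_selection(sel_tables)
  retention <- dplyr::bind_rows(lapply(sel_tables, function(s) {
    dplyr::mutate(s$table, response = s$response, .before = 1)
  }))
  emit(function(obj, path) readr::write_tsv(obj, path), retention,
       "selection_retention.tsv")
  emit(function(obj, path) readr::write_tsv(obj, path), sel_summary,
       "selection_summary.tsv")

  manifest <- list(
    package = "holonet",
    version = as.character(utils::packageVersion("holonet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    # digest excludes the output location so reruns elsewhere compare equal
    config_digest = rlang::hash(unclass(config)[setdiff(names(config), "out_dir")]),
    outputs = basename(outs)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
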