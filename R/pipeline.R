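#' Assemble a run configuration
#'
#' Bundles all pipeline parameters with the input objects or file paths.
#' Inputs may be given in-memory (`matrix`, `precursors`, `domains`) or as
#' paths (`peptide_table`, `design_file`, `fasta`, `domain_file`).
#'
#' @param matrix An `AbundanceMatrix`, or `NULL` to read from files.
#' @param precursors Named precursor sequences, or `NULL` to read `fasta`.
#' @param domains Optional domain annotation data.frame.
#' @param peptide_table,design_file,fasta,domain_file Optional input paths.
#' @param ref_quantile Reference-peptide quantile (default 0.1).
#' @param max_missing_per_group Missingness filter threshold (default 4).
#' @param alpha,min_fold Significance gate (defaults 0.05, 2).
#' @param min_treated,max_control Marker thresholds (defaults 9, 2).
#' @param top_k,min_agreement Consensus selection parameters (defaults 10, 2).
#' @param run_selection Run consensus feature selection (default TRUE).
#' @param seed Master seed recorded in the manifest.
#' @param out_dir Optional output directory; when given, result tables, a
#'   summary JSON and a run manifest are written.
#' @return list of class `run_config`.
#' @export
run_config <- function(matrix = NULL, precursors = NULL, domains = NULL,
                       peptide_table = NULL, design_file = NULL, fasta = NULL,
                       domain_file = NULL,
                       ref_quantile = 0.1, max_missing_per_group = 4L,
                       alpha = 0.05, min_fold = 2,
                       min_treated = 9L, max_control = 2L,
                       top_k = 10L, min_agreement = 2L,
                       run_selection = TRUE, seed = 1L, out_dir = NULL) {
  paths <- c(peptide_table, design_file, fasta, domain_file)
  missing_paths <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing_paths))
    stop("input path(s) do not exist: ", paste(missing_paths, collapse = ", "))
  structure(as.list(environment())[setdiff(ls(), c("paths", "missing_paths"))],
            class = "run_config")
}

#' Run the full microdialysate peptidomics analysis
#'
#' Stage order: total-intensity normalization, stable-reference normalization,
#' presence/absence marker detection on the pre-filter matrix (markers fail
#' the missingness filter by construction), missingness filtering, paired
#' t-test with BH adjustment and the fold gate, positional annotation,
#' probe-yield summary, replicate correlation, clustering, and consensus
#' feature selection on the imputed significant submatrix. Deterministic for
#' a fixed seed.
#'
#' @param config A `run_config`.
#' @return list of class `dialyspep_run`: `normalized` (AbundanceMatrix),
#'   `model`, `markers`, `filtered`, `differential`, `annotation`,
#'   `probe_yield`, `correlation`, `clustering`, `length_comparison`,
#'   `consensus`, `summary`.
#' @export
run_full_analysis <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  mat <- stage("ingest", {
    if (!is.null(config$matrix)) config$matrix
    else read_peptide_table(config$peptide_table,
                            read_design(config$design_file))
  })
  precursors <- if (!is.null(config$precursors)) config$precursors
    else if (!is.null(config$fasta)) stage("ingest",
                                           read_precursor_fasta(config$fasta))
    else NULL
  domains <- if (!is.null(config$domains)) config$domains
    else if (!is.null(config$domain_file)) stage("ingest",
                                                 read_domain_table(config$domain_file))
    else NULL

  norm <- stage("normalize", normalize_two_stage(mat, config$ref_quantile))
  markers <- stage("markers",
                   detect_treatment_specific(norm$matrix,
                                             config$min_treated,
                                             config$max_control))
  filtered <- stage("filter",
                    filter_by_missingness(norm$matrix,
                                          config$max_missing_per_group))
  diff <- stage("differential",
                run_differential(filtered, alpha = config$alpha,
                                 min_fold = config$min_fold))
  annotation <- if (!is.null(precursors)) stage("annotate", {
    rec <- filtered$records
    plen <- nchar(precursors)[rec$accession]
    plen[is.na(plen)] <- Inf
    ann <- data.frame(
      peptide_id = rec$peptide_id,
      length = nchar(rec$sequence),
      terminal_class = classify_terminal_fragment(rec$start, rec$end, plen),
      acetylated = has_nterm_acetyl(rec$modifications),
      stringsAsFactors = FALSE)
    dib <- flanked_by_dibasic(rec, precursors)
    ann$dibasic_flanked <- dib$dibasic_flanked
    if (!is.null(domains)) {
      ov <- map_known_domain_overlaps(rec, domains)
      hit <- ov$peptide_id[ov$overlap != "NONE"]
      ann$in_known_domain <- ann$peptide_id %in% hit
    }
    ann
  }) else NULL
  probe_yield <- stage("probe_yield", summarize_probe_yield(norm$matrix))
  correlation <- stage("correlation", replicate_correlation(filtered))
  sig_ids <- diff$peptide_id[diff$significant]
  lengths_sig <- nchar(filtered$records$sequence[
    match(sig_ids, filtered$records$peptide_id)])
  dirs <- diff$direction[diff$significant]
  len_cmp <- if (sum(dirs == "up") > 0 && sum(dirs == "down") > 0)
    stage("lengths", compare_length_distributions(lengths_sig[dirs == "down"],
                                                  lengths_sig[dirs == "up"]))
  else NULL
  clustering <- NULL
  consensus <- NULL
  if (length(sig_ids) >= 2L) {
    imputed <- stage("impute", impute_missing(subset_peptides(filtered, sig_ids)))
    clustering <- stage("cluster", cluster_samples(imputed, k = 2L))
    if (isTRUE(config$run_selection))
      consensus <- stage("select",
                         consensus_feature_selection(
                           imputed, imputed$design$phase,
                           top_k = config$top_k,
                           min_agreement = config$min_agreement,
                           seed = config$seed))
  }
  s <- attr(diff, "summary")
  summary <- list(
    n_detected = nrow(mat$values),
    n_filtered = nrow(filtered$values),
    n_tested = s$n_tested,
    n_significant = s$n_significant,
    n_up = s$n_up, n_down = s$n_down,
    n_proteins_significant = s$n_proteins_significant,
    n_markers = sum(markers$marker),
    mean_length_up = if (any(dirs == "up")) mean(lengths_sig[dirs == "up"])
      else NA_real_,
    mean_length_down = if (any(dirs == "down")) mean(lengths_sig[dirs == "down"])
      else NA_real_,
    ks_length_p = if (!is.null(len_cmp)) len_cmp$p else NA_real_,
    probe_yield_mean = probe_yield$yield_mean,
    probe_yield_sd = probe_yield$yield_sd,
    seed = config$seed)
  result <- structure(
    list(normalized = norm$matrix, model = norm$model, markers = markers,
         filtered = filtered, differential = diff, annotation = annotation,
         probe_yield = probe_yield, correlation = correlation,
         clustering = clustering, length_comparison = len_cmp,
         consensus = consensus, summary = summary),
    class = "dialyspep_run")
  if (!is.null(config$out_dir)) write_run_outputs(result, config)
  result
}

#' @export
print.dialyspep_run <- function(x, ...) {
  s <- x$summary
  cat("dialyspep run summary\n")
  cat(sprintf("  detected peptides:   %d\n", s$n_detected))
  cat(sprintf("  after filter:        %d\n", s$n_filtered))
  cat(sprintf("  significant:         %d (%d up, %d down) from %s proteins\n",
              s$n_significant, s$n_up, s$n_down, s$n_proteins_significant))
  cat(sprintf("  treatment markers:   %d\n", s$n_markers))
  cat(sprintf("  mean length up/down: %.2f / %.2f (KS p = %.3g)\n",
              s$mean_length_up, s$mean_length_down, s$ks_length_p))
  cat(sprintf("  probe yield:         %.2f +/- %.2f peptides\n",
              s$probe_yield_mean, s$probe_yield_sd))
  invisible(x)
}

write_run_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  cleanup <- function() if (length(written)) unlink(written)
  ok <- FALSE
  on.exit(if (!ok) cleanup())
  wt <- function(obj, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    written <<- c(written, p)
    p
  }
  wt(as.data.frame(result$differential), "differential.tsv")
  wt(result$markers, "markers.tsv")
  if (!is.null(result$annotation)) wt(result$annotation, "annotation.tsv")
  if (!is.null(result$consensus))
    wt(data.frame(peptide_id = result$consensus$consensus), "consensus.tsv")
  p <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(result$summary, p, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  written <- c(written, p)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dialyspep")),
    seed = config$seed,
    parameters = config[c("ref_quantile", "max_missing_per_group", "alpha",
                          "min_fold", "min_treated", "max_control", "top_k",
                          "min_agreement")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  pm <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  written <- c(written, pm)
  ok <- TRUE
  invisible(written)
}
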