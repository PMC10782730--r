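#' Paired two-tailed t-test on abundances
#'
#' Classical paired t on per-subject differences after complete-pair deletion
#' (subjects missing a value in either phase are dropped). Zero-variance
#' differences yield a flagged degenerate result (t = 0, p = 1) rather than an
#' error, so identical phases are handled gracefully.
#'
#' @param control,treated Numeric vectors paired by position (one entry per
#'   subject); `NA` for missing.
#' @return list `t_stat`, `df`, `p_raw`, `n_pairs`, `degenerate`.
#' @export
paired_t_test <- function(control, treated) {
  if (length(control) != length(treated))
    stop("control and treated must be paired by subject (equal length)")
  ok <- !is.na(control) & !is.na(treated)
  n <- sum(ok)
  if (n < 3L) stop("insufficient complete pairs (", n, " < 3)")
  d <- treated[ok] - control[ok]
  s <- stats::sd(d)
  if (s == 0)
    return(list(t_stat = 0, df = n - 1L, p_raw = 1, n_pairs = n,
                degenerate = TRUE))
  t_stat <- mean(d) / (s / sqrt(n))
  list(t_stat = t_stat, df = n - 1L,
       p_raw = 2 * stats::pt(abs(t_stat), df = n - 1L, lower.tail = FALSE),
       n_pairs = n, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (smallest FDR at which each hypothesis is
#' rejected), with input validation; order of the input is preserved.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Paired differential abundance analysis
#'
#' Runs the paired t-test per peptide on the linear abundance scale (the test
#' is applied directly to normalized abundances; set `log2_transform = TRUE`
#' to test log2 abundances instead), adjusts with Benjamini-Hochberg and
#' applies the significance gate: adjusted p < `alpha` AND fold change
#' (max of ratio and its reciprocal) >= `min_fold`.
#'
#' @param mat A normalized, missingness-filtered `AbundanceMatrix`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_fold Minimum fold change (default 2).
#' @param log2_transform Test log2 abundances instead of linear (default
#'   FALSE).
#' @param min_pairs Minimum complete pairs required per peptide (default 3);
#'   peptides below it get `NA` statistics and are never significant.
#' @return data.frame of per-peptide results (class `differential_table`) with
#'   a `summary` attribute (`n_tested`, `n_significant`, `n_up`, `n_down`,
#'   `n_proteins_significant`).
#' @export
run_differential <- function(mat, alpha = 0.05, min_fold = 2,
                             log2_transform = FALSE, min_pairs = 3L) {
  ctrl <- design_samples(mat$design, "control")
  trt <- design_samples(mat$design, "treated")
  vc <- mat$values[, ctrl, drop = FALSE]
  vt <- mat$values[, trt, drop = FALSE]
  if (log2_transform) { vc <- log2(vc); vt <- log2(vt) }
  n <- nrow(vc)
  res <- data.frame(peptide_id = mat$records$peptide_id,
                    accession = mat$records$accession,
                    n_pairs = NA_integer_, mean_control = NA_real_,
                    mean_treated = NA_real_, ratio = NA_real_,
                    fold_change = NA_real_, direction = NA_character_,
                    t_stat = NA_real_, df = NA_integer_, p_raw = NA_real_,
                    p_adj = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ok <- !is.na(vc[i, ]) & !is.na(vt[i, ])
    res$n_pairs[i] <- sum(ok)
    res$mean_control[i] <- mean(vc[i, ][!is.na(vc[i, ])])
    res$mean_treated[i] <- mean(vt[i, ][!is.na(vt[i, ])])
    if (sum(ok) < min_pairs) next
    tt <- paired_t_test(vc[i, ], vt[i, ])
    res$t_stat[i] <- tt$t_stat; res$df[i] <- tt$df
    res$p_raw[i] <- tt$p_raw; res$degenerate[i] <- tt$degenerate
  }
  res$ratio <- res$mean_treated / res$mean_control
  res$fold_change <- pmax(res$ratio, 1 / res$ratio)
  res$direction <- ifelse(res$ratio > 1, "up", "down")
  tested <- !is.na(res$p_raw)
  res$p_adj[tested] <- bh_adjust(res$p_raw[tested])
  classify_differential(res, alpha = alpha, min_fold = min_fold)
}

#' Apply the significance gate and summarize
#'
#' significant iff adjusted p < `alpha` AND fold change >= `min_fold`;
#' annotates the records and attaches summary counts.
#'
#' @param records A differential-results data.frame with `p_adj`,
#'   `fold_change`, `direction`, `accession` columns.
#' @inheritParams run_differential
#' @return The annotated data.frame (class `differential_table`) with a
#'   `summary` attribute.
#' @export
classify_differential <- function(records, alpha = 0.05, min_fold = 2) {
  records$significant <- !is.na(records$p_adj) &
    records$p_adj < alpha & records$fold_change >= min_fold
  sig <- records[records$significant, , drop = FALSE]
  attr(records, "summary") <- list(
    n_tested = sum(!is.na(records$p_adj)),
    n_significant = nrow(sig),
    n_up = sum(sig$direction == "up"),
    n_down = sum(sig$direction == "down"),
    n_proteins_significant =
      if (!is.null(sig$accession)) length(unique(sig$accession)) else NA_integer_)
  class(records) <- c("differential_table", "data.frame")
  records
}

#' @export
print.differential_table <- function(x, ...) {
  s <- attr(x, "summary")
  NextMethod()
  cat(sprintf("\n%d tested; %d significant (%d up, %d down) from %s proteins\n",
              s$n_tested, s$n_significant, s$n_up, s$n_down,
              s$n_proteins_significant))
  invisible(x)
}

#' Per-peptide normality screen
#'
#' Advisory Kolmogorov-Smirnov normality report on the paired differences of
#' each peptide (standardized, Lilliefors-style use of `ks.test` against the
#' fitted normal). Never used as an exclusion rule.
#'
#' @param mat An `AbundanceMatrix`.
#' @return data.frame `peptide_id`, `n_pairs`, `ks_p`.
#' @export
normality_screen <- function(mat) {
  ctrl <- design_samples(mat$design, "control")
  trt <- design_samples(mat$design, "treated")
  out <- data.frame(peptide_id = mat$records$peptide_id,
                    n_pairs = NA_integer_, ks_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat$values))) {
    d <- mat$values[i, trt] - mat$values[i, ctrl]
    d <- d[!is.na(d)]
    out$n_pairs[i] <- length(d)
    if (length(d) >= 3 && stats::sd(d) > 0)
      out$ks_p[i] <- suppressWarnings(
        stats::ks.test(d, "pnorm", mean(d), stats::sd(d))$p.value)
  }
  out
}

#' Compare two length distributions
#'
#' Two-sample Kolmogorov-Smirnov test (asymptotic two-sided p), as used to
#' compare the lengths of down- and upregulated peptides.
#'
#' @param lengths_a,lengths_b Non-empty numeric vectors.
#' @return list `D`, `p`.
#' @export
compare_length_distributions <- function(lengths_a, lengths_b) {
  if (!length(lengths_a) || !length(lengths_b))
    stop("both length samples must be non-empty")
  ks <- suppressWarnings(stats::ks.test(lengths_a, lengths_b, exact = FALSE))
  list(D = unname(ks$statistic), p = unname(ks$p.value))
}

#' Spearman correlation between biological replicates
#'
#' Symmetric sample-by-sample Spearman matrix on pairwise-complete
#' observations with average-rank ties; pairs sharing fewer than 3 present
#' values are reported as `NA`.
#'
#' @param mat An `AbundanceMatrix`.
#' @param min_shared Minimum shared present values per pair (default 3).
#' @return Numeric sample-by-sample matrix with unit diagonal.
#' @export
replicate_correlation <- function(mat, min_shared = 3L) {
  v <- mat$values
  if (ncol(v) < 2L) stop("need at least 2 samples")
  rho <- suppressWarnings(
    stats::cor(v, method = "spearman", use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(v))
  rho[shared < min_shared] <- NA_real_
  diag(rho) <- 1
  rho
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on a chosen peptide subset (typically
#' the significant peptides after imputation): Euclidean distance, complete
#' linkage, deterministic given the sample order.
#'
#' @param mat A complete (imputed) `AbundanceMatrix`, or a numeric matrix with
#'   samples in columns.
#' @param peptide_ids Optional subset of peptides to cluster on.
#' @param k Number of flat clusters to cut (default 2).
#' @return list `hclust` (the tree), `clusters` (named integer vector at `k`).
#' @export
cluster_samples <- function(mat, peptide_ids = NULL, k = 2L) {
  v <- if (inherits(mat, "AbundanceMatrix")) mat$values else as.matrix(mat)
  if (!is.null(peptide_ids)) v <- v[peptide_ids, , drop = FALSE]
  if (anyNA(v)) stop("missing values present; impute first (impute_missing)")
  if (ncol(v) == 1L)
    return(list(hclust = NULL,
                clusters = stats::setNames(1L, colnames(v))))
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                      method = "complete")
  clusters <- if (ncol(v) >= k) stats::cutree(hc, k = k) else
    stats::setNames(seq_len(ncol(v)), colnames(v))
  list(hclust = hc, clusters = clusters)
}

#' Offline over-representation analysis
#'
#' Hypergeometric upper-tail test of a query protein set against
#' user-supplied gene sets over a fixed universe. A term is retained when it
#' has at least `min_hits` query proteins AND fold enrichment at least
#' `min_fold`; BH adjustment is applied across the retained terms.
#'
#' @param query Character vector of query accessions (subset of `universe`).
#' @param gene_sets Named list, term id to accession vector.
#' @param universe Character vector of background accessions.
#' @param min_hits Minimum query proteins in the term (default 4).
#' @param min_fold Minimum fold enrichment (default 4).
#' @return data.frame, one row per term: hit counts, `fold_enrichment`, `p`,
#'   `p_adj` (retained terms only), `retained`.
#' @export
enrich_over_representation <- function(query, gene_sets, universe,
                                       min_hits = 4L, min_fold = 4.0) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe) || !length(query)) stop("empty universe or query")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  n_universe <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(gene_sets[[term]]), universe)
    hits <- length(intersect(members, query))
    n_term <- length(members)
    fold <- if (n_term == 0) NA_real_ else
      (hits / n_query) / (n_term / n_universe)
    p <- if (n_term == 0) NA_real_ else
      stats::phyper(hits - 1L, n_term, n_universe - n_term, n_query,
                    lower.tail = FALSE)
    data.frame(term_id = term, n_query_in_term = hits, n_term = n_term,
               n_query = n_query, n_universe = n_universe,
               fold_enrichment = fold, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$retained <- !is.na(out$p) & out$n_query_in_term >= min_hits &
    out$fold_enrichment >= min_fold
  out$p_adj <- NA_real_
  if (any(out$retained)) out$p_adj[out$retained] <- bh_adjust(out$p[out$retained])
  out[order(out$p), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (term, description, members...; tab-separated).
#' @return Named list of accession vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[`, character(1), 1L))
}
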