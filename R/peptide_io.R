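#' Construct a paired study design
#'
#' A paired microdialysis design: each subject contributes exactly one sample
#' per phase through the same probe. Sample identifiers are
#' `<subject>_<phase>`.
#'
#' @param subjects Character vector of subject identifiers.
#' @param phases Character vector of exactly two phase labels; the first is the
#'   control phase, the second the treated phase.
#' @return A data.frame with columns `sample`, `subject`, `phase`.
#' @examples
#' study_design(c("r01", "r02"))
#' @export
study_design <- function(subjects, phases = c("control", "treated")) {
  subjects <- as.character(subjects)
  if (length(phases) != 2L) stop("a paired design needs exactly two phases")
  if (anyDuplicated(subjects)) stop("duplicated subject identifiers")
  d <- expand.grid(phase = phases, subject = subjects,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("subject", "phase")]
  d$sample <- paste(d$subject, d$phase, sep = "_")
  rownames(d) <- NULL
  structure(d[, c("sample", "subject", "phase")],
            phases = phases, class = c("study_design", "data.frame"))
}

#' @rdname study_design
#' @param design A `study_design` data.frame.
#' @param phase Either `"control"` or `"treated"`.
#' @return `design_samples()`: the sample ids belonging to one phase, ordered
#'   by subject.
#' @export
design_samples <- function(design, phase) {
  ph <- design_phases(design)
  phase <- match.arg(phase, c("control", "treated"))
  lab <- if (phase == "control") ph[1] else ph[2]
  d <- design[design$phase == lab, ]
  d$sample[order(match(d$subject, unique(design$subject)))]
}

design_phases <- function(design) {
  ph <- attr(design, "phases")
  if (is.null(ph)) ph <- unique(design$phase)
  if (length(ph) != 2L) stop("design must carry exactly two phases")
  ph
}

validate_design <- function(design) {
  stopifnot(all(c("sample", "subject", "phase") %in% names(design)))
  tab <- table(design$subject, design$phase)
  if (any(tab != 1L))
    stop("paired design violated: every subject needs exactly one sample per phase")
  invisible(design)
}

#' Read a study design table
#'
#' Delimited text with columns `sample`, `subject`, `phase` (delimiter
#' auto-detected among tab, comma, semicolon).
#'
#' @param path Path to the design file.
#' @return A `study_design` data.frame.
#' @export
read_design <- function(path) {
  d <- read_delim_auto(path)
  need <- c("sample", "subject", "phase")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design file lacks mandatory column(s): ",
                         paste(miss, collapse = ", "))
  phases <- unique(d$phase)
  if (length(phases) != 2L) stop("design must contain exactly two phases")
  out <- structure(d[, need], phases = phases,
                   class = c("study_design", "data.frame"))
  validate_design(out)
  out
}

#' @rdname read_design
#' @param design Design to write.
#' @param sep Field delimiter.
#' @export
write_design <- function(design, path, sep = "\t") {
  utils::write.table(as.data.frame(design)[, c("sample", "subject", "phase")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Delimiter auto-detection: supplementary tables circulate as TSV, CSV and
# semicolon-CSV; pick the candidate that splits the header into most fields.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  counts <- vapply(c("\t", ",", ";"),
                   function(s) length(strsplit(header, s, fixed = TRUE)[[1]]),
                   integer(1))
  c("\t", ",", ";")[which.max(counts)]
}

read_delim_auto <- function(path) {
  utils::read.table(path, sep = detect_delim(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", na.strings = "")
}

#' Construct an abundance matrix
#'
#' The central container: a peptide-by-sample grid of positive abundances with
#' `NA` for missing (not-detected) cells, the peptide annotation records, and
#' the paired design.
#'
#' @param records data.frame with columns `peptide_id`, `sequence`,
#'   `accession`, `start`, `end`, and optionally `gene_symbol`,
#'   `modifications` (semicolon-separated `index:name` pairs, `""` for none).
#' @param design A `study_design`.
#' @param values Numeric matrix, one row per record (rownames = peptide ids),
#'   one column per design sample; `NA` encodes a missing cell.
#' @param length_bounds Permitted peptide-length range; violations warn.
#' @return An object of class `AbundanceMatrix`.
#' @export
abundance_matrix <- function(records, design, values, length_bounds = c(7L, 50L)) {
  validate_design(design)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("peptide_id", "sequence", "accession", "start", "end")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(records$gene_symbol)) records$gene_symbol <- NA_character_
  if (is.null(records$modifications)) records$modifications <- ""
  records$modifications[is.na(records$modifications)] <- ""
  if (anyDuplicated(records$peptide_id))
    stop("peptide_id values must be unique")
  bad <- which(!(records$start >= 1 & records$start <= records$end))
  if (length(bad)) stop("invalid positions (need 1 <= start <= end) at row(s): ",
                        paste(utils::head(bad), collapse = ", "))
  len <- nchar(records$sequence)
  bad <- which(records$end - records$start + 1L != len)
  if (length(bad)) stop("end - start + 1 != sequence length at row(s): ",
                        paste(utils::head(bad), collapse = ", "))
  if (!is.null(length_bounds)) {
    out_of_bounds <- len < length_bounds[1] | len > length_bounds[2]
    if (any(out_of_bounds))
      warning(sum(out_of_bounds), " peptide(s) outside the length bounds [",
              length_bounds[1], ", ", length_bounds[2], "]")
  }
  values <- as.matrix(values)
  if (nrow(values) != nrow(records))
    stop("values grid must have one row per peptide record")
  if (!setequal(colnames(values), design$sample))
    stop("values columns must match the design samples")
  values <- values[, design$sample, drop = FALSE]
  rownames(values) <- records$peptide_id
  if (any(values[!is.na(values)] <= 0))
    stop("abundances must be positive; zeros are not a missing-value code")
  structure(list(records = records, design = design, values = values),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d peptides x %d samples (%d subjects, paired)\n",
              nrow(x$values), ncol(x$values), length(unique(x$design$subject))))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' Subset an AbundanceMatrix by peptide ids
#' @param x An `AbundanceMatrix`.
#' @param peptide_ids Ids to keep (order preserved).
#' @return The subsetted `AbundanceMatrix`.
#' @export
subset_peptides <- function(x, peptide_ids) {
  idx <- match(peptide_ids, x$records$peptide_id)
  if (anyNA(idx)) stop("unknown peptide id(s): ",
                       paste(utils::head(peptide_ids[is.na(idx)]), collapse = ", "))
  abundance_matrix(x$records[idx, , drop = FALSE], x$design,
                   x$values[idx, , drop = FALSE], length_bounds = NULL)
}

#' Read a peptide quantification table
#'
#' Delimited text mirroring the supplementary-table schema: annotation columns
#' `peptide_id` (optional), `sequence`, `accession`, `gene_symbol` (optional),
#' `start`, `end`, `modifications` (optional), followed by one abundance column
#' per design sample named `<subject>_<phase>`. Empty cells denote missing
#' (not detected); zeros are rejected. Rows duplicating the peptide identity
#' tuple (sequence, modifications, accession, start) are collapsed.
#'
#' @param path Path to the table.
#' @param design A `study_design` whose samples resolve the abundance columns.
#' @param collapse Policy for duplicate identity rows: `"sum"` (default, warns)
#'   or `"error"`.
#' @param length_bounds Permitted peptide-length range (warning on violation);
#'   `NULL` disables the check.
#' @return An `AbundanceMatrix`.
#' @export
read_peptide_table <- function(path, design, collapse = c("sum", "error"),
                               length_bounds = c(7L, 50L)) {
  collapse <- match.arg(collapse)
  validate_design(design)
  d <- read_delim_auto(path)
  if (!nrow(d)) stop("peptide table is empty: ", path)
  need <- c("sequence", "accession", "start", "end")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("peptide table lacks mandatory column(s): ",
                         paste(miss, collapse = ", "))
  miss_samp <- setdiff(design$sample, names(d))
  if (length(miss_samp)) stop("design mismatch: no abundance column for sample(s): ",
                              paste(miss_samp, collapse = ", "))
  extra <- setdiff(names(d), c("peptide_id", "sequence", "accession",
                               "gene_symbol", "start", "end", "modifications",
                               design$sample))
  if (length(extra)) stop("design mismatch: abundance column(s) not in design: ",
                          paste(extra, collapse = ", "))
  vals <- as.matrix(d[, design$sample, drop = FALSE])
  storage.mode(vals) <- "double"
  nonpos <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
  if (nrow(nonpos)) stop("non-positive abundance at table row ", nonpos[1, 1],
                         " (abundances must be positive or empty)")
  if (is.null(d$modifications)) d$modifications <- ""
  d$modifications[is.na(d$modifications)] <- ""
  if (is.null(d$gene_symbol)) d$gene_symbol <- NA_character_
  key <- paste(d$sequence, d$modifications, d$accession, d$start, sep = "\r")
  if (anyDuplicated(key)) {
    if (collapse == "error") stop("duplicate peptide identity rows present")
    warning("collapsing ", sum(duplicated(key)),
            " duplicate peptide identity row(s) by summing abundances")
    first <- !duplicated(key)
    grp <- match(key, key[first])
    vals <- rowsum_na(vals, grp)
    d <- d[first, , drop = FALSE]
  }
  if (is.null(d$peptide_id) || anyNA(d$peptide_id))
    d$peptide_id <- sprintf("pep%05d", seq_len(nrow(d)))
  records <- d[, c("peptide_id", "sequence", "accession", "gene_symbol",
                   "start", "end", "modifications")]
  rownames(records) <- NULL
  abundance_matrix(records, design, vals, length_bounds = length_bounds)
}

# rowsum that treats NA as absent but keeps all-NA groups NA (sum of nothing
# is "not detected", not zero).
rowsum_na <- function(vals, grp) {
  out <- rowsum(ifelse(is.na(vals), 0, vals), grp)
  n_present <- rowsum((!is.na(vals)) * 1L, grp)
  out[n_present == 0] <- NA_real_
  out
}

#' Write a peptide table
#'
#' Emits the same schema `read_peptide_table()` accepts; missing cells are
#' written as empty fields so a write-then-read round trip is lossless.
#'
#' @param mat An `AbundanceMatrix`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_peptide_table <- function(mat, path, sep = "\t") {
  vals <- mat$values
  out <- cbind(mat$records,
               as.data.frame(vals, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read precursor protein sequences from FASTA
#'
#' Accession is the first whitespace-delimited token of the header; the
#' UniProt `sp|ACC|NAME` / `tr|ACC|NAME` dialect is unwrapped to `ACC`.
#'
#' @param path FASTA file path.
#' @return Named character vector, accession to uppercase amino-acid sequence.
#' @export
read_precursor_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  up <- grepl("^(sp|tr)\\|", acc)
  acc[up] <- vapply(strsplit(acc[up], "|", fixed = TRUE), `[`, character(1), 2L)
  dup <- unique(acc[duplicated(acc)])
  if (length(dup)) stop("duplicate accession(s) in FASTA: ",
                        paste(dup, collapse = ", "))
  stats::setNames(toupper(as.character(seqs)), acc)
}

#' @rdname read_precursor_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_precursor_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Validate peptide positions against precursor sequences
#'
#' Reports, per peptide, whether its coordinates fit inside the precursor and
#' whether `precursor[start..end]` equals the peptide sequence. Mismatches are
#' reported, never fatal.
#'
#' @param mat An `AbundanceMatrix` (or its `records` data.frame).
#' @param precursors Named vector from [read_precursor_fasta()].
#' @return data.frame `peptide_id`, `accession_known`, `in_bounds`,
#'   `sequence_match`.
#' @export
validate_peptide_positions <- function(mat, precursors) {
  rec <- if (inherits(mat, "AbundanceMatrix")) mat$records else mat
  plen <- nchar(precursors)[rec$accession]
  known <- !is.na(plen)
  in_bounds <- known & rec$start >= 1 & rec$end <= plen
  seq_match <- rep(FALSE, nrow(rec))
  idx <- which(in_bounds)
  seq_match[idx] <- substr(precursors[rec$accession[idx]],
                           rec$start[idx], rec$end[idx]) == rec$sequence[idx]
  data.frame(peptide_id = rec$peptide_id, accession_known = known,
             in_bounds = in_bounds, sequence_match = seq_match,
             stringsAsFactors = FALSE)
}

#' Read / write a known-domain annotation table
#'
#' Columns `accession`, `domain_name`, `start`, `end` (1-based inclusive),
#' e.g. secretoneurin = Scg2 184-216.
#'
#' @param path File path.
#' @return data.frame of domain annotations.
#' @export
read_domain_table <- function(path) {
  d <- read_delim_auto(path)
  need <- c("accession", "domain_name", "start", "end")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("domain table lacks mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$start > d$end)) stop("domain with start > end")
  d[, need]
}

#' @rdname read_domain_table
#' @param domains data.frame of domain annotations.
#' @param sep Field delimiter.
#' @export
write_domain_table <- function(domains, path, sep = "\t") {
  utils::write.table(domains, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Parse "idx:name;idx:name" modification strings into a two-column matrix.
parse_modifications <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(index = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(index = as.integer(vapply(parts, `[`, character(1), 1L)),
             name = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}
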