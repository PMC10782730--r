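AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Classify a peptide as terminal fragment, full length or internal
#'
#' N-terminal fragments start at precursor position 1 (intact initiator) or 2
#' (after initiator-methionine loss, the default `met_loss_window` of 2);
#' C-terminal fragments end at the precursor's last residue. A peptide doing
#' both is the (near-)full-length protein.
#'
#' @param start,end 1-based inclusive peptide coordinates (vectorized).
#' @param precursor_length Length of the precursor protein (vectorized).
#' @param met_loss_window Largest start position still counted as the protein
#'   N-terminus (default 2 = Met-loss allowed).
#' @return Character vector in
#'   `{"N_TERMINAL","C_TERMINAL","FULL_LENGTH","INTERNAL"}`.
#' @export
classify_terminal_fragment <- function(start, end, precursor_length,
                                       met_loss_window = 2L) {
  if (any(end > precursor_length, na.rm = TRUE))
    stop("peptide end position exceeds precursor length")
  n_side <- start <= met_loss_window
  c_side <- end == precursor_length
  out <- rep("INTERNAL", length(start))
  out[n_side & !c_side] <- "N_TERMINAL"
  out[!n_side & c_side] <- "C_TERMINAL"
  out[n_side & c_side] <- "FULL_LENGTH"
  out
}

# acetyl (case-insensitive) on the peptide's first residue
has_nterm_acetyl <- function(modifications) {
  vapply(modifications, function(s) {
    m <- parse_modifications(s)
    any(m$index == 1L & grepl("acetyl", m$name, ignore.case = TRUE))
  }, logical(1), USE.NAMES = FALSE)
}

#' Cross-tabulate N-terminal fragments and N-terminal acetylation
#'
#' The 2x2 composition table of a peptidome: terminal class (N-terminal
#' fragment vs all peptides) against presence of an N-terminal acetyl
#' modification, with column percentages.
#'
#' @param records Peptide records data.frame (or an `AbundanceMatrix`).
#' @param precursors Named precursor sequences (accession to sequence); used
#'   to resolve precursor lengths. Records with unknown accessions are counted
#'   as non-terminal.
#' @param met_loss_window See [classify_terminal_fragment()].
#' @return list `counts` (2x2 + sums), `percent`, `n_terminal`,
#'   `n_acetylated_nterm`, `classes` (per-peptide terminal class).
#' @export
summarize_terminal_and_acetyl <- function(records, precursors,
                                          met_loss_window = 2L) {
  rec <- if (inherits(records, "AbundanceMatrix")) records$records else records
  if (!nrow(rec)) {
    counts <- matrix(0L, 2, 2, dimnames = list(
      c("no_acetyl", "acetyl"), c("N_terminal", "all")))
    return(list(counts = counts, percent = counts * NA_real_,
                n_terminal = 0L, n_acetylated_nterm = 0L,
                classes = character(0)))
  }
  plen <- nchar(precursors)[rec$accession]
  plen[is.na(plen)] <- Inf   # unknown precursor: cannot be C-terminal
  classes <- classify_terminal_fragment(rec$start, rec$end, plen,
                                        met_loss_window)
  is_nterm <- classes %in% c("N_TERMINAL", "FULL_LENGTH")
  acetyl <- has_nterm_acetyl(rec$modifications)
  counts <- rbind(
    no_acetyl = c(sum(is_nterm & !acetyl), sum(!acetyl)),
    acetyl    = c(sum(is_nterm & acetyl),  sum(acetyl)))
  colnames(counts) <- c("N_terminal", "all")
  tot <- colSums(counts)
  tot[tot == 0] <- NA_real_
  percent <- 100 * sweep(counts, 2L, tot, `/`)
  list(counts = counts, percent = percent,
       n_terminal = sum(is_nterm),
       n_acetylated_nterm = sum(is_nterm & acetyl),
       classes = classes)
}

#' Extract cleavage-site residue contexts
#'
#' For every peptide two contexts are emitted, one per terminus. Positions
#' follow Schechter-Berger nomenclature: P4..P1 upstream of the scissile
#' bond, P1'..P4' downstream. For the N-side context P1 is the precursor
#' residue immediately before the peptide start; for the C-side context P1 is
#' the peptide's last residue. Where the precursor ends, positions are padded
#' with the gap symbol `-` (never invented residues).
#'
#' @param records Peptide records data.frame (or `AbundanceMatrix`).
#' @param precursors Named precursor sequences.
#' @param width Residues on each side of the cleavage site (default 4).
#' @return data.frame `peptide_id`, `side` (`"N"`/`"C"`), `context`
#'   (`2*width`-character string, P4..P4'). Peptides whose positions mismatch
#'   the precursor are skipped with a warning.
#' @export
extract_cleavage_contexts <- function(records, precursors, width = 4L) {
  rec <- if (inherits(records, "AbundanceMatrix")) records$records else records
  report <- validate_peptide_positions(rec, precursors)
  ok <- report$in_bounds & report$sequence_match
  if (any(!ok))
    warning(sum(!ok), " peptide(s) skipped: position/sequence mismatch ",
            "against the precursor")
  rec <- rec[ok, , drop = FALSE]
  if (!nrow(rec))
    return(data.frame(peptide_id = character(0), side = character(0),
                      context = character(0), stringsAsFactors = FALSE))
  window <- function(seqs, centers) {
    # context around the bond between position `centers` and `centers`+1
    vapply(seq_along(seqs), function(i) {
      s <- seqs[i]; c0 <- centers[i]; n <- nchar(s)
      pos <- (c0 - width + 1L):(c0 + width)
      chars <- ifelse(pos >= 1L & pos <= n,
                      substring(s, pos, pos), "-")
      paste(chars, collapse = "")
    }, character(1))
  }
  seqs <- precursors[rec$accession]
  data.frame(
    peptide_id = rep(rec$peptide_id, 2L),
    side = rep(c("N", "C"), each = nrow(rec)),
    context = c(window(seqs, rec$start - 1L), window(seqs, rec$end)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Positional residue frequency matrix for cleavage contexts
#'
#' 20-residue by position frequency matrix over contexts (optionally one side
#' only). Gap symbols are excluded from each position's denominator so
#' protein-terminal peptides do not distort the logo. Optionally returns
#' information-content (bits) weighted heights for logo rendering.
#'
#' @param contexts data.frame from [extract_cleavage_contexts()].
#' @param side `"both"` (default), `"N"` or `"C"`.
#' @param information_content If TRUE, scale each column by its information
#'   content in bits (log2(20) - entropy).
#' @return Numeric matrix, 20 residues x positions `P4..P1,P1'..P4'`; without
#'   IC weighting every column sums to 1 (over positions with any residue).
#' @export
residue_frequency_matrix <- function(contexts, side = c("both", "N", "C"),
                                     information_content = FALSE) {
  side <- match.arg(side)
  if (side != "both") contexts <- contexts[contexts$side == side, , drop = FALSE]
  if (!nrow(contexts)) stop("no cleavage contexts to tabulate")
  w <- nchar(contexts$context[1]) / 2L
  positions <- c(paste0("P", w:1), paste0("P", 1:w, "'"))
  chars <- do.call(rbind, strsplit(contexts$context, ""))
  freq <- matrix(0, nrow = length(AA20), ncol = 2L * w,
                 dimnames = list(AA20, positions))
  for (j in seq_len(2L * w)) {
    col <- chars[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tab <- table(factor(col, levels = AA20))
      freq[, j] <- as.numeric(tab) / length(col)
    }
  }
  if (information_content) {
    ic <- apply(freq, 2L, function(f) {
      f <- f[f > 0]
      log2(length(AA20)) + sum(f * log2(f))
    })
    freq <- sweep(freq, 2L, ic, `*`)
  }
  freq
}

#' Classify peptide overlap with known domains
#'
#' Interval relation of each peptide against each domain annotation on the
#' same precursor: `CONTAINED` when the peptide lies fully inside the domain,
#' `PARTIAL` when the intervals intersect otherwise, `NONE` when disjoint.
#'
#' @param records Peptide records data.frame (or `AbundanceMatrix`).
#' @param domains data.frame from [read_domain_table()].
#' @return data.frame `peptide_id`, `accession`, `domain_name`, `overlap`.
#' @export
map_known_domain_overlaps <- function(records, domains) {
  rec <- if (inherits(records, "AbundanceMatrix")) records$records else records
  out <- merge(rec[, c("peptide_id", "accession", "start", "end")],
               domains, by = "accession",
               suffixes = c("", "_domain"))
  if (!nrow(out))
    return(data.frame(peptide_id = character(0), accession = character(0),
                      domain_name = character(0), overlap = character(0),
                      stringsAsFactors = FALSE))
  contained <- out$start_domain <= out$start & out$end <= out$end_domain
  intersects <- out$start <= out$end_domain & out$start_domain <= out$end
  out$overlap <- ifelse(contained, "CONTAINED",
                        ifelse(intersects, "PARTIAL", "NONE"))
  out[, c("peptide_id", "accession", "domain_name", "overlap")]
}

#' Detect dibasic (Lys/Arg pair) flanks
#'
#' TRUE when the two residues immediately preceding the peptide start AND the
#' two immediately following its end are each a basic pair (both residues in
#' {K, R}) - the canonical prohormone-convertase excision signature. At a
#' protein terminus the corresponding side is FALSE (the pair does not exist).
#'
#' @param records Peptide records data.frame (or `AbundanceMatrix`).
#' @param precursors Named precursor sequences.
#' @return data.frame `peptide_id`, `upstream_pair`, `downstream_pair`
#'   (the residue pairs or `NA`), `upstream_dibasic`, `downstream_dibasic`,
#'   `dibasic_flanked`.
#' @export
flanked_by_dibasic <- function(records, precursors) {
  rec <- if (inherits(records, "AbundanceMatrix")) records$records else records
  seqs <- precursors[rec$accession]
  n <- nchar(seqs)
  up <- ifelse(rec$start >= 3L & !is.na(seqs),
               substr(seqs, rec$start - 2L, rec$start - 1L), NA_character_)
  down <- ifelse(!is.na(seqs) & rec$end + 2L <= n,
                 substr(seqs, rec$end + 1L, rec$end + 2L), NA_character_)
  is_basic_pair <- function(p) !is.na(p) & grepl("^[KR][KR]$", p)
  up_ok <- is_basic_pair(up)
  down_ok <- is_basic_pair(down)
  data.frame(peptide_id = rec$peptide_id,
             upstream_pair = up, downstream_pair = down,
             upstream_dibasic = up_ok, downstream_dibasic = down_ok,
             dibasic_flanked = up_ok & down_ok,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Peptide length distribution summary
#'
#' @param records Peptide records data.frame (or `AbundanceMatrix`), or a
#'   numeric vector of lengths.
#' @return list `lengths`, `mean`, `median`, `range`, `histogram` (table of
#'   counts per length).
#' @export
length_distribution <- function(records) {
  lengths <- if (is.numeric(records)) records else {
    rec <- if (inherits(records, "AbundanceMatrix")) records$records else records
    nchar(rec$sequence)
  }
  list(lengths = lengths,
       mean = mean(lengths), median = stats::median(lengths),
       range = if (length(lengths)) range(lengths) else c(NA, NA),
       histogram = table(lengths))
}
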