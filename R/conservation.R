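.snpcons_env <- new.env(parent = emptyenv())

#' Per-column conservation statistics at a variant position
#'
#' Counts, among the non-human rows of the alignment, how many carry the
#' unmutated human residue at the column corresponding to `prot_pos`.
#' Rows gapped at the column carry no residue evidence and are excluded
#' from both the numerator and the denominator; the human row is excluded
#' so the score measures homolog support, not self-match.
#'
#' @param aln A `MultipleAlignment` (the combined ortholog+paralog protein
#'   alignment for classification).
#' @param prot_pos 1-based human reference position.
#' @param human_ref_aa The unmutated human residue; must match the human row.
#' @return List of class `ColumnStats`: `position_i`, `a_i` (matching
#'   homolog rows), `n_h` (valid homolog rows), `wpc` (percent).
#' @export
column_stats <- function(aln, prot_pos, human_ref_aa) {
  col <- ref_to_column(aln, prot_pos)
  human_char <- aln$matrix[aln$human_row_id, col]
  if (!missing(human_ref_aa) && human_char != toupper(human_ref_aa)) {
    stop("human row has '", human_char, "' at position ", prot_pos,
         " but query reference is '", human_ref_aa, "'", call. = FALSE)
  }
  others <- aln$matrix[setdiff(aln$ids, aln$human_row_id), col]
  valid <- others != "-"
  n_h <- sum(valid)
  a_i <- sum(others[valid] == human_char)
  if (n_h == 0L) {
    stop(structure(
      class = c("snpcons_undefined_wpc", "error", "condition"),
      list(message = paste0("WPC undefined at position ", prot_pos,
                            ": all homolog rows are gapped"),
           call = NULL, position = prot_pos)))
  }
  structure(list(position_i = prot_pos, a_i = a_i, n_h = n_h,
                 wpc = 100 * a_i / n_h),
            class = "ColumnStats")
}

#' Weighted protein conservation (WPC) score
#'
#' Percent of valid homolog rows (both orthologs and paralogs, gapped rows
#' excluded) whose residue at the variant column matches the unmutated
#' human residue: `100 * a_i / n_h`. Note this scores conservation of the
#' human residue specifically, not overall column conservation.
#'
#' @inheritParams column_stats
#' @return Percent in `[0, 100]`.
#' @export
wpc_score <- function(aln, prot_pos, human_ref_aa) {
  column_stats(aln, prot_pos, human_ref_aa)$wpc
}

#' Percent conservation of the human character at a position
#'
#' Same count as [wpc_score()] but usable on any alignment kind (protein or
#' nucleotide, ortholog or paralog): percent of valid non-human rows
#' matching the human row's character at the mapped column.
#'
#' @param aln A `MultipleAlignment`.
#' @param pos 1-based position in the ungapped human reference sequence.
#' @return Percent in `[0, 100]`.
#' @export
percent_conservation <- function(aln, pos) {
  column_stats(aln, pos)$wpc
}

#' PSIC-style positional profile
#'
#' Log-odds profile of residue frequencies per alignment column against a
#' uniform background, with a redundancy discount: each row is weighted by
#' the reciprocal of the number of identical aligned rows, so duplicated
#' sequences contribute once. With pseudocount 1 per residue the profile
#' value for residue `r` at column `c` is
#' `log(20 * (m_rc + 1) / (n_c + 20))`, where `m_rc` is the weighted count
#' of `r` at `c` and `n_c` the total weight of ungapped rows at `c`.
#' All rows (including the human reference) contribute.
#'
#' @param aln A protein `MultipleAlignment` with at least two rows.
#' @param pseudocount Pseudocount per residue (default 1).
#' @return Object of class `PsicProfile`: 20 x ncol matrix `values`,
#'   per-row `weights`, `colmap` (human position -> column), `pseudocount`.
#' @export
psic_profile <- function(aln, pseudocount = 1) {
  if (aln$kind != "protein") {
    stop("PSIC profile is defined on protein alignments", call. = FALSE)
  }
  rows <- apply(aln$matrix, 1L, paste, collapse = "")
  mult <- table(rows)
  w <- 1 / as.numeric(mult[rows])
  ncols <- ncol(aln$matrix)
  counts <- matrix(0, nrow = length(AA_LETTERS), ncol = ncols,
                   dimnames = list(AA_LETTERS, NULL))
  for (i in seq_along(rows)) {
    ch <- aln$matrix[i, ]
    ok <- ch %in% AA_LETTERS
    if (any(ok)) {
      idx <- cbind(match(ch[ok], AA_LETTERS), which(ok))
      counts[idx] <- counts[idx] + w[i]
    }
  }
  n_c <- colSums(counts)
  values <- log(sweep(counts + pseudocount, 2L,
                      (n_c + 20 * pseudocount) / 20, "/"))
  structure(list(values = values, weights = w, colmap = aln$colmap,
                 pseudocount = pseudocount),
            class = "PsicProfile")
}

#' PSIC substitution score
#'
#' Absolute difference of the profile values of the reference and alternate
#' residues at the variant column. Symmetric and nonnegative; zero for a
#' synonymous "substitution". Stop-gains are handled upstream and are not
#' scored.
#'
#' @param profile A `PsicProfile` computed on the same alignment used for
#'   WPC scoring.
#' @param prot_pos 1-based human reference position.
#' @param ref_aa,alt_aa Single-letter residues.
#' @return Nonnegative score.
#' @export
psic_delta <- function(profile, prot_pos, ref_aa, alt_aa) {
  if (alt_aa == "*" || ref_aa == "*") {
    stop("stop-gains are not scored by the PSIC profile", call. = FALSE)
  }
  if (prot_pos < 1L || prot_pos > length(profile$colmap)) {
    stop("position ", prot_pos, " outside profile", call. = FALSE)
  }
  col <- profile$colmap[[prot_pos]]
  unname(abs(profile$values[toupper(ref_aa), col] -
               profile$values[toupper(alt_aa), col]))
}

load_blosum62 <- function() {
  if (is.null(.snpcons_env$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "snpcons")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#")]
    letters <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    rows <- strsplit(trimws(lines[-1L]), "\\s+")
    m <- t(vapply(rows, function(r) as.integer(r[-1L]),
                  integer(length(letters))))
    dimnames(m) <- list(vapply(rows, `[[`, character(1), 1L), letters)
    .snpcons_env$blosum62 <- m
  }
  .snpcons_env$blosum62
}

#' BLOSUM62 substitution score
#'
#' Looks up the published BLOSUM62 matrix (shipped with the package in NCBI
#' matrix format). Vectorized over pairs.
#'
#' @param aa1,aa2 Single-letter amino acids (stop `*`, ambiguity codes B/Z/X
#'   allowed as in the published matrix).
#' @return Integer substitution score(s).
#' @export
blosum62 <- function(aa1, aa2) {
  m <- load_blosum62()
  aa1 <- toupper(aa1); aa2 <- toupper(aa2)
  bad <- unique(c(aa1[!aa1 %in% rownames(m)], aa2[!aa2 %in% colnames(m)]))
  if (length(bad)) {
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m[cbind(aa1, aa2)])
}

#' Per-variant conservation report
#'
#' Assembles the conservation evidence for one variant: WPC on the combined
#' classification alignment, PSIC substitution score, BLOSUM62 score, and
#' the percent conservation in each of the four report alignments
#' (protein/nucleotide x ortholog/paralog) that are supplied. Nucleotide
#' percentages are suppressed (NA) when the codon mapping of the
#' substitution is ambiguous, since no definitive DNA position exists.
#'
#' @param query A `VariantQuery`.
#' @param gene A `GeneRecord`.
#' @param combined_aln Combined ortholog+paralog protein alignment.
#' @param report_alns Named list with any of `protein_ortholog`,
#'   `protein_paralog`, `nucleotide_ortholog`, `nucleotide_paralog`.
#' @param records Optional known-variant data.frame for the window count.
#' @param config A `PipelineConfig`.
#' @return One-row data.frame of class `ConservationReport`.
#' @export
conservation_report <- function(query, gene, combined_aln,
                                report_alns = list(),
                                records = NULL,
                                config = pipeline_config()) {
  wpc <- wpc_score(combined_aln, query$prot_pos, query$ref_aa)
  psic <- if (query$alt_aa %in% AA_LETTERS) {
    psic_delta(psic_profile(combined_aln), query$prot_pos,
               query$ref_aa, query$alt_aa)
  } else NA_real_
  blos <- blosum62(query$ref_aa, query$alt_aa)
  mapping <- map_protein_to_cds(gene, query$prot_pos, query$ref_aa,
                                query$alt_aa)
  pct <- function(kind, name) {
    a <- report_alns[[name]]
    if (is.null(a)) return(NA_real_)
    if (kind == "nucleotide") {
      if (mapping$ambiguous || nrow(mapping$candidate_changes) == 0L) {
        return(NA_real_)  # no definitive DNA location
      }
      percent_conservation(a, mapping$candidate_changes$cds_pos[1L])
    } else {
      percent_conservation(a, query$prot_pos)
    }
  }
  n_window <- if (is.null(records)) NA_integer_ else {
    recs <- records[records$gene == query$gene &
                      records$classification %in%
                        c("pathogenic", "unspecified_functional") &
                      abs(records$prot_pos - query$prot_pos) <= config$range_aa, ]
    nrow(recs)
  }
  out <- data.frame(
    gene = query$gene, prot_pos = query$prot_pos,
    ref_aa = query$ref_aa, alt_aa = query$alt_aa,
    wpc = wpc, psic = psic, blosum62 = blos,
    pct_protein_ortholog = pct("protein", "protein_ortholog"),
    pct_protein_paralog = pct("protein", "protein_paralog"),
    pct_nucleotide_ortholog = pct("nucleotide", "nucleotide_ortholog"),
    pct_nucleotide_paralog = pct("nucleotide", "nucleotide_paralog"),
    known_in_window = n_window,
    ambiguous_codon = mapping$ambiguous,
    stringsAsFactors = FALSE)
  class(out) <- c("ConservationReport", class(out))
  out
}
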