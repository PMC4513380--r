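#' Map a protein substitution onto the coding sequence
#'
#' Locates the CDS codon of a protein position by anchor search: a window of
#' ten residues starting at the query position (taken backwards when the
#' position lies within ten residues of the C terminus, and shrunk for
#' proteins shorter than ten residues) is matched against the translation of
#' every nucleotide offset of the CDS, and a unique match is required. All
#' single-nucleotide edits of the reference codon that produce the alternate
#' residue are then enumerated; more than one candidate marks the mapping
#' ambiguous, in which case nucleotide-level conservation cannot be reported
#' (protein-level classification is unaffected).
#'
#' @param gene A `GeneRecord`.
#' @param prot_pos 1-based protein position.
#' @param ref_aa Reference residue (must match the protein sequence).
#' @param alt_aa Alternate residue; `*` for a stop-gain.
#' @param anchor_len Anchor window length in residues (default 10).
#' @return An object of class `CodonMapping`: `prot_pos`,
#'   `cds_codon_start`, `ref_codon`, `candidate_changes` (data.frame with
#'   `nt_offset`, `ref_nt`, `alt_nt`, `cds_pos`), `ambiguous`.
#' @export
map_protein_to_cds <- function(gene, prot_pos, ref_aa, alt_aa,
                               anchor_len = 10L) {
  np <- nchar(gene$protein_seq)
  prot_pos <- as.integer(prot_pos)
  if (prot_pos < 1L || prot_pos > np) {
    stop("protein position ", prot_pos, " outside 1..", np, call. = FALSE)
  }
  seq_ref <- substr(gene$protein_seq, prot_pos, prot_pos)
  if (seq_ref != ref_aa) {
    stop("reference residue mismatch at ", prot_pos, ": expected ", seq_ref,
         call. = FALSE)
  }
  anchor_len <- min(anchor_len, np)
  if (prot_pos + anchor_len - 1L <= np) {
    a_start <- prot_pos
  } else {
    a_start <- np - anchor_len + 1L  # within anchor_len of the terminus
  }
  anchor <- substr(gene$protein_seq, a_start, a_start + anchor_len - 1L)

  # search the translation of every nucleotide offset (all three frames)
  cds <- gene$cds_seq
  L <- nchar(cds)
  hits <- integer(0)
  for (f in 0:2) {
    sub <- substr(cds, f + 1L, L - ((L - f) %% 3L))
    if (nchar(sub) < 3L * anchor_len) next
    aa <- translate_cds(sub)
    occ <- gregexpr(anchor, aa, fixed = TRUE)[[1L]]
    if (occ[1L] != -1L) hits <- c(hits, f + 3L * (occ - 1L) + 1L)
  }
  if (length(hits) == 0L) {
    stop("anchor '", anchor, "' not found in CDS of ", gene$symbol,
         ": inconsistent inputs", call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop("anchor '", anchor, "' matches the CDS of ", gene$symbol,
         " at ", length(hits), " positions: ambiguous mapping",
         call. = FALSE)
  }
  codon_start <- hits + 3L * (prot_pos - a_start)
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  cand <- enumerate_codon_changes(ref_codon, alt_aa)
  if (nrow(cand)) cand$cds_pos <- codon_start + cand$nt_offset - 1L
  structure(
    list(prot_pos = prot_pos,
         cds_codon_start = codon_start,
         ref_codon = ref_codon,
         candidate_changes = cand,
         ambiguous = nrow(cand) > 1L),
    class = "CodonMapping"
  )
}

#' Enumerate single-nucleotide codon edits producing a target residue
#'
#' Scans all nine single-nucleotide neighbours of `codon` and keeps those
#' translating to `target_aa` (which may be `*`).
#'
#' @param codon 3-nt reference codon.
#' @param target_aa Target residue.
#' @return data.frame with columns `nt_offset` (1..3), `ref_nt`, `alt_nt`.
#' @export
enumerate_codon_changes <- function(codon, target_aa) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L)
  out <- list()
  for (off in 1:3) {
    ref_nt <- substr(codon, off, off)
    for (nt in setdiff(NT_LETTERS, ref_nt)) {
      mutated <- codon
      substr(mutated, off, off) <- nt
      if (unname(Biostrings::GENETIC_CODE[mutated]) == target_aa) {
        out[[length(out) + 1L]] <-
          data.frame(nt_offset = off, ref_nt = ref_nt, alt_nt = nt,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(nt_offset = integer(0), ref_nt = character(0),
                      alt_nt = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Map a CDS substitution to protein coordinates
#'
#' @param gene A `GeneRecord`.
#' @param cds_pos 1-based CDS nucleotide position.
#' @param ref_nt Reference nucleotide (must match the CDS).
#' @param alt_nt Alternate nucleotide.
#' @return List: `prot_pos`, `ref_aa`, `alt_aa`, `synonymous` flag.
#' @export
map_cds_to_protein <- function(gene, cds_pos, ref_nt, alt_nt) {
  cds <- gene$cds_seq
  cds_pos <- as.integer(cds_pos)
  if (cds_pos < 1L || cds_pos > nchar(cds)) {
    stop("CDS position ", cds_pos, " outside 1..", nchar(cds), call. = FALSE)
  }
  ref_nt <- toupper(ref_nt); alt_nt <- toupper(alt_nt)
  have <- substr(cds, cds_pos, cds_pos)
  if (have != ref_nt) {
    stop("reference nucleotide mismatch at CDS position ", cds_pos,
         ": expected ", have, call. = FALSE)
  }
  prot_pos <- as.integer(ceiling(cds_pos / 3))
  codon_start <- 3L * (prot_pos - 1L) + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cds_pos - codon_start + 1L, cds_pos - codon_start + 1L) <- alt_nt
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  list(prot_pos = prot_pos, ref_aa = ref_aa, alt_aa = alt_aa,
       synonymous = identical(ref_aa, alt_aa))
}

#' Locate a mutated flanking sequence in the CDS
#'
#' The flank starts at the mutated nucleotide, so the search restores the
#' first nucleotide to each of the four possible reference bases and
#' requires a unique exact match of the leading 100 nt in the CDS.
#'
#' @param gene A `GeneRecord`.
#' @param flank Nucleotide string, at least 100 nt, first nt mutated.
#' @return 1-based CDS position of the mutated nucleotide.
#' @export
locate_flank <- function(gene, flank) {
  flank <- toupper(gsub("\\s", "", flank))
  if (nchar(flank) < 100L) {
    stop("flanking sequence must be at least 100 nt (got ", nchar(flank), ")",
         call. = FALSE)
  }
  if (grepl("[^ACGT]", flank)) {
    stop("flanking sequence contains non-ACGT characters", call. = FALSE)
  }
  probe_tail <- substr(flank, 2L, 100L)
  hits <- integer(0)
  for (nt in NT_LETTERS) {
    probe <- paste0(nt, probe_tail)
    occ <- gregexpr(probe, gene$cds_seq, fixed = TRUE)[[1L]]
    if (occ[1L] != -1L) hits <- c(hits, as.integer(occ))
  }
  hits <- sort(unique(hits))
  if (length(hits) == 0L) {
    stop("flanking sequence not found in CDS of ", gene$symbol, call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop("flanking sequence matches the CDS of ", gene$symbol, " at ",
         length(hits), " positions: ambiguous", call. = FALSE)
  }
  hits
}

#' Stop-gain auto-pathogenicity under the nonsense-mediated-decay rule
#'
#' A premature stop codon is auto-called pathogenic when its first
#' nucleotide lies strictly more than `nmd_distance_nt` (default 50)
#' nucleotides upstream of the last exon-exon junction in spliced CDS
#' coordinates. Stops at or downstream of the junction, stops within the
#' distance, and single-exon genes all fall through to the ordinary
#' pipeline.
#'
#' @param gene A `GeneRecord` (supplies the exon structure).
#' @param mapping A `CodonMapping` for the stop-gain variant.
#' @param config A `PipelineConfig` (supplies `nmd_distance_nt`).
#' @return Logical flag.
#' @export
stop_gain_auto_pathogenic <- function(gene, mapping, config = pipeline_config()) {
  if (length(gene$exons) < 2L) return(FALSE)
  junction <- sum(head(gene$exons, -1L))  # CDS position of last nt before the final junction
  distance <- junction - mapping$cds_codon_start
  distance > config$nmd_distance_nt
}
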