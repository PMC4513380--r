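#' @importFrom stats runif setNames approx
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT_LETTERS <- c("A", "C", "G", "T")

#' Translate a coding sequence
#'
#' Translates an in-frame nucleotide string with the standard genetic code.
#' Stop codons are rendered as `*`.
#'
#' @param nt Nucleotide string; length must be a multiple of 3.
#' @return Amino-acid string (may contain `*`).
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  }
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    bad <- codons[is.na(aa)][1L]
    stop("untranslatable codon '", bad, "'", call. = FALSE)
  }
  paste(aa, collapse = "")
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Construct a validated gene record
#'
#' Bundles the reference protein sequence, the spliced CDS (including the
#' stop codon) and the exon structure of one gene. The CDS must translate
#' exactly to the protein (stop dropped) and the exon lengths must sum to
#' the CDS length; violations raise immediately so that downstream
#' coordinate arithmetic can assume consistency.
#'
#' @param symbol HUGO-style gene symbol.
#' @param protein_seq Amino-acid string, 1-based positions.
#' @param cds_seq Nucleotide string, length divisible by 3, stop codon last.
#' @param exons Integer vector of exon lengths in spliced CDS coordinates
#'   (nucleotides), in splicing order.
#' @return An object of class `GeneRecord`.
#' @export
gene_record <- function(symbol, protein_seq, cds_seq, exons) {
  protein_seq <- toupper(gsub("\\s", "", protein_seq))
  cds_seq <- toupper(gsub("\\s", "", cds_seq))
  exons <- as.integer(exons)
  if (!nzchar(symbol)) stop("gene symbol must be non-empty", call. = FALSE)
  if (nchar(cds_seq) %% 3L != 0L) {
    stop("CDS length of '", symbol, "' is not a multiple of 3", call. = FALSE)
  }
  tr <- translate_cds(cds_seq)
  if (substr(tr, nchar(tr), nchar(tr)) == "*") {
    tr <- substr(tr, 1L, nchar(tr) - 1L)
  }
  if (!identical(tr, protein_seq)) {
    stop("CDS of '", symbol, "' does not translate to its protein sequence",
         call. = FALSE)
  }
  if (any(exons <= 0L)) {
    stop("exon lengths must be strictly positive", call. = FALSE)
  }
  if (sum(exons) != nchar(cds_seq)) {
    stop("exon lengths of '", symbol, "' sum to ", sum(exons),
         " but CDS length is ", nchar(cds_seq), call. = FALSE)
  }
  structure(
    list(symbol = symbol, protein_seq = protein_seq,
         cds_seq = cds_seq, exons = exons),
    class = "GeneRecord"
  )
}

#' @export
print.GeneRecord <- function(x, ...) {
  cat("<GeneRecord> ", x$symbol, ": ", nchar(x$protein_seq), " aa, ",
      nchar(x$cds_seq), " nt CDS, ", length(x$exons), " exon(s)\n", sep = "")
  invisible(x)
}

#' Construct a validated multiple alignment
#'
#' Rows are equal-length aligned strings over residues (or nucleotides) and
#' the gap character `-`. One row is the designated human reference; its
#' ungapped sequence anchors the column/position map used by all scoring.
#' `.` and `*` are rejected in rows to avoid gap/stop confusion.
#'
#' @param kind `"protein"` or `"nucleotide"`.
#' @param ids Character vector of row identifiers (unique).
#' @param seqs Character vector of aligned strings, same length as `ids`.
#' @param human_row_id Identifier of the human reference row.
#' @param source `"ortholog"`, `"paralog"` or `"combined"`.
#' @return An object of class `MultipleAlignment` with precomputed
#'   position-to-column map for the human row.
#' @export
multiple_alignment <- function(kind = c("protein", "nucleotide"),
                               ids, seqs,
                               human_row_id,
                               source = c("combined", "ortholog", "paralog")) {
  kind <- match.arg(kind)
  source <- match.arg(source)
  seqs <- toupper(seqs)
  if (length(ids) != length(seqs)) {
    stop("ids and seqs differ in length", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate row identifiers", call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  }
  if (any(grepl("[.*]", seqs))) {
    stop("alignment rows may not contain '.' or '*'; use '-' for gaps",
         call. = FALSE)
  }
  if (!human_row_id %in% ids) {
    stop("human reference row '", human_row_id, "' not found in alignment",
         call. = FALSE)
  }
  if (length(ids) < 2L) {
    stop("alignment needs at least one non-human row", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  human <- mat[human_row_id, ]
  colmap <- which(human != "-")   # colmap[p] = alignment column of position p
  structure(
    list(kind = kind, ids = ids, matrix = mat,
         human_row_id = human_row_id, source = source,
         colmap = colmap),
    class = "MultipleAlignment"
  )
}

#' @export
print.MultipleAlignment <- function(x, ...) {
  cat("<MultipleAlignment> ", x$kind, "/", x$source, ": ",
      length(x$ids), " rows x ", ncol(x$matrix), " columns (human: ",
      x$human_row_id, ")\n", sep = "")
  invisible(x)
}

#' Ungapped sequence of one alignment row
#' @param aln A `MultipleAlignment`.
#' @param id Row identifier; defaults to the human reference row.
#' @return Plain sequence string with gaps removed.
#' @export
ungapped_row <- function(aln, id = aln$human_row_id) {
  paste(aln$matrix[id, aln$matrix[id, ] != "-"], collapse = "")
}

#' Map a human reference position to an alignment column
#' @param aln A `MultipleAlignment`.
#' @param pos 1-based position in the ungapped human reference sequence.
#' @return Integer column index.
#' @export
ref_to_column <- function(aln, pos) {
  if (pos < 1L || pos > length(aln$colmap)) {
    stop("position ", pos, " outside human reference (length ",
         length(aln$colmap), ")", call. = FALSE)
  }
  aln$colmap[[pos]]
}

#' Pipeline configuration
#'
#' Collects every tunable of the classification pipeline. Defaults are the
#' calibrated operating point: hotspot screening on, PSIC off, WPC
#' pathogenicity cutoff 49 percent (40 percent when PSIC is enabled, with
#' PSIC benign cutoff 1.03), phenotype/hotspot window half-width 100 amino
#' acids, and the 50-nt nonsense-mediated-decay distance for stop-gains.
#'
#' @param range_aa Window half-width in amino acids (default 100).
#' @param use_psic Use the PSIC-style profile score as a benign filter.
#' @param use_hotspot Use known-variant hotspot screening.
#' @param use_stopgain Auto-call qualifying stop-gains pathogenic.
#' @param psic_cutoff PSIC benign cutoff (strictly below is benign).
#' @param wpc_cutoff_with_psic WPC percent cutoff when PSIC is enabled.
#' @param wpc_cutoff_default WPC percent cutoff in the default (PSIC-off) mode.
#' @param nmd_distance_nt Stop-gain distance rule threshold in nucleotides.
#' @param seed Integer seed for any randomized downstream step.
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(range_aa = 100L,
                            use_psic = FALSE,
                            use_hotspot = TRUE,
                            use_stopgain = TRUE,
                            psic_cutoff = 1.03,
                            wpc_cutoff_with_psic = 40,
                            wpc_cutoff_default = 49,
                            nmd_distance_nt = 50L,
                            seed = 1L) {
  range_aa <- as.integer(range_aa)
  if (is.na(range_aa) || range_aa < 0L) {
    stop("range_aa must be a nonnegative integer", call. = FALSE)
  }
  for (w in c(wpc_cutoff_with_psic, wpc_cutoff_default)) {
    if (is.na(w) || w < 0 || w > 100) {
      stop("WPC cutoffs must lie in [0, 100]", call. = FALSE)
    }
  }
  if (nmd_distance_nt < 0L) stop("nmd_distance_nt must be >= 0", call. = FALSE)
  structure(
    list(range_aa = range_aa,
         use_psic = isTRUE(use_psic),
         use_hotspot = isTRUE(use_hotspot),
         use_stopgain = isTRUE(use_stopgain),
         psic_cutoff = psic_cutoff,
         wpc_cutoff_with_psic = wpc_cutoff_with_psic,
         wpc_cutoff_default = wpc_cutoff_default,
         nmd_distance_nt = as.integer(nmd_distance_nt),
         seed = as.integer(seed)),
    class = "PipelineConfig"
  )
}

#' Read a pipeline configuration from YAML or JSON
#' @param path File path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown config fields: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Normalized variant query
#'
#' Internal constructor used by [parse_variant_query()] and the batch
#' reader; validates against the gene record.
#' @noRd
variant_query <- function(gene, prot_pos, ref_aa, alt_aa,
                          cds_pos = NA_integer_, ref_nt = NA_character_,
                          alt_nt = NA_character_,
                          origin = c("protein", "cds", "flank", "batch")) {
  origin <- match.arg(origin)
  prot_pos <- as.integer(prot_pos)
  np <- nchar(gene$protein_seq)
  if (prot_pos < 1L || prot_pos > np) {
    stop("protein position ", prot_pos, " outside 1..", np, call. = FALSE)
  }
  seq_ref <- substr(gene$protein_seq, prot_pos, prot_pos)
  if (seq_ref != ref_aa) {
    stop("reference residue mismatch at position ", prot_pos, ": query has ",
         ref_aa, " but sequence has ", seq_ref, call. = FALSE)
  }
  if (!alt_aa %in% c(AA_LETTERS, "*")) {
    stop("invalid alternate residue '", alt_aa, "'", call. = FALSE)
  }
  if (!is.na(cds_pos) && as.integer(ceiling(cds_pos / 3)) != prot_pos) {
    stop("CDS position ", cds_pos, " does not fall in codon ", prot_pos,
         call. = FALSE)
  }
  structure(
    list(gene = gene$symbol, prot_pos = prot_pos,
         ref_aa = ref_aa, alt_aa = alt_aa,
         cds_pos = as.integer(cds_pos), ref_nt = ref_nt, alt_nt = alt_nt,
         origin = origin),
    class = "VariantQuery"
  )
}

#' @export
print.VariantQuery <- function(x, ...) {
  cat("<VariantQuery> ", x$gene, " p.", x$ref_aa, x$prot_pos, x$alt_aa,
      if (!is.na(x$cds_pos)) paste0(" (c.", x$cds_pos, x$ref_nt, ">", x$alt_nt, ")"),
      " [", x$origin, "]\n", sep = "")
  invisible(x)
}
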