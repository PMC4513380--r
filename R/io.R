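#' Read a FASTA file
#'
#' Minimal strict FASTA reader. Sequences are uppercased, whitespace inside
#' records is dropped, record order is preserved, and malformed input is
#' reported with the offending line number (a contract the generic readers
#' do not provide).
#'
#' @param path File path.
#' @return Named list of sequence strings (names are full header lines
#'   without the leading `>`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("FASTA parse error at line ", lineno[1L],
         ": expected '>' header", call. = FALSE)
  }
  ids <- sub("^>\\s*", "", lines[is_hdr])
  if (any(!nzchar(ids))) {
    stop("FASTA parse error at line ", lineno[is_hdr][!nzchar(ids)][1L],
         ": empty header", call. = FALSE)
  }
  rec <- cumsum(is_hdr)
  empty <- setdiff(seq_along(ids), unique(rec[!is_hdr]))
  if (length(empty)) {
    stop("FASTA parse error at line ", lineno[is_hdr][empty[1L]],
         ": record '", ids[empty[1L]], "' has no sequence", call. = FALSE)
  }
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]), function(x) {
    toupper(gsub("\\s", "", paste(x, collapse = "")))
  }, character(1))
  setNames(as.list(unname(seqs)), ids)
}

#' Write sequences to a FASTA file
#' @param seqs Named list or character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, max(nchar(s), 1L), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

parse_clustal <- function(lines, path) {
  if (!grepl("^(CLUSTAL|MUSCLE)", lines[1L])) {
    stop("not a CLUSTAL file (missing header): ", path, call. = FALSE)
  }
  body <- lines[-1L]
  acc <- list()
  order <- character(0)
  for (ln in body) {
    if (grepl("^\\s*$", ln)) next
    if (grepl("^\\s", ln)) next  # consensus line
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)", ln))[[1L]]
    if (length(m) < 3L) next
    id <- m[2L]
    chunk <- gsub("[0-9]", "", m[3L])  # strip optional position counters
    if (!id %in% order) order <- c(order, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], chunk)
  }
  if (length(order) == 0L) stop("no alignment rows in ", path, call. = FALSE)
  setNames(as.list(unlist(acc[order])), order)
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or block-interleaved CLUSTAL (`.aln`) files into a
#' [multiple_alignment()]. Gap characters `.` are normalized to `-` before
#' validation. The human reference row is located by exact `human_id` match
#' when given, otherwise by an id equal to, prefixed with, or suffixed with
#' `human`.
#'
#' @param path File path.
#' @param kind `"protein"` or `"nucleotide"`.
#' @param dialect `"auto"` (default), `"fasta"` or `"clustal"`.
#' @param human_id Identifier of the human row, or `NULL` to autodetect.
#' @param source Alignment provenance: `"combined"`, `"ortholog"`, `"paralog"`.
#' @return A `MultipleAlignment`.
#' @export
read_alignment <- function(path, kind = c("protein", "nucleotide"),
                           dialect = c("auto", "fasta", "clustal"),
                           human_id = NULL,
                           source = c("combined", "ortholog", "paralog")) {
  kind <- match.arg(kind)
  dialect <- match.arg(dialect)
  source <- match.arg(source)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (grepl("^(CLUSTAL|MUSCLE)", first)) "clustal" else "fasta"
  }
  rows <- if (dialect == "clustal") {
    parse_clustal(readLines(path, warn = FALSE), path)
  } else {
    read_fasta(path)
  }
  seqs <- gsub(".", "-", unlist(rows), fixed = TRUE)
  ids <- names(rows)
  if (is.null(human_id)) {
    hit <- which(ids == "human" | grepl("^human[_|]", ids) |
                   grepl("[_|]human$", ids))
    if (length(hit) != 1L) {
      stop("cannot identify a unique human row in ", path,
           "; pass human_id explicitly", call. = FALSE)
    }
    human_id <- ids[hit]
  }
  multiple_alignment(kind = kind, ids = ids, seqs = unname(seqs),
                     human_row_id = human_id, source = source)
}

#' Write a multiple alignment as aligned FASTA
#' @param aln A `MultipleAlignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  write_fasta(setNames(as.list(seqs), aln$ids), path)
}

#' Default classification-vocabulary aliases
#'
#' Maps the tokens used by humsavar/ClinVar-style exports onto the internal
#' closed vocabulary `pathogenic`, `benign`, `unspecified_functional`.
#' @return Named character vector (names are input tokens, lowercased).
#' @export
classification_aliases <- function() {
  c(pathogenic = "pathogenic",
    benign = "benign",
    unspecified_functional = "unspecified_functional",
    disease = "pathogenic",
    polymorphism = "benign",
    unclassified = "unspecified_functional")
}

#' Read a known-variant table
#'
#' Reads a humsavar/ClinVar-like TSV with header columns `gene`, `prot_pos`,
#' `ref_aa`, `alt_aa`, `classification`, `phenotype`. Classification tokens
#' are mapped through `aliases`; unknown tokens raise a row-level error with
#' the file line number. Duplicate records are preserved.
#'
#' @param path TSV path.
#' @param aliases Named character vector mapping input tokens (lowercased)
#'   to the closed vocabulary; defaults to [classification_aliases()].
#' @return data.frame of known-variant records.
#' @export
read_known_variants <- function(path, aliases = classification_aliases()) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                   na.strings = NULL)
  req <- c("gene", "prot_pos", "ref_aa", "alt_aa", "classification", "phenotype")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("known-variant table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cls <- unname(aliases[tolower(df$classification)])
  if (anyNA(cls) && nrow(df) > 0L) {
    bad <- which(is.na(cls))[1L]
    stop("unknown classification '", df$classification[bad], "' at line ",
         bad + 1L, " of ", path, call. = FALSE)
  }
  out <- data.frame(gene = df$gene,
                    prot_pos = as.integer(df$prot_pos),
                    ref_aa = toupper(df$ref_aa),
                    alt_aa = toupper(df$alt_aa),
                    classification = cls,
                    phenotype = df$phenotype,
                    stringsAsFactors = FALSE)
  if (anyNA(out$prot_pos) || any(out$prot_pos < 1L)) {
    stop("non-positive or unparseable prot_pos in ", path, call. = FALSE)
  }
  out
}

#' Write a known-variant table
#' @param records data.frame as returned by [read_known_variants()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_known_variants <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an exon-structure table
#'
#' TSV with columns `gene`, `exon_index`, `length_nt`, giving exon lengths
#' in spliced CDS coordinates.
#'
#' @param path TSV path.
#' @return Named list: gene symbol -> integer vector of exon lengths in
#'   splicing order.
#' @export
read_exons <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "exon_index", "length_nt")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("exon table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$gene), function(g) {
    as.integer(g$length_nt[order(g$exon_index)])
  })
}

#' Parse a single variant query
#'
#' Accepted forms: protein notation `p.<ref><pos><alt>` (alt may be `*` for
#' a stop-gain), CDS notation `c.<pos><ref>><alt>`, or a raw flanking
#' nucleotide sequence of at least 100 nt whose first nucleotide is the
#' mutated one. CDS and flank inputs are resolved to protein coordinates via
#' the codon map; the reference residue/nucleotide is checked against the
#' gene record.
#'
#' @param text Query text.
#' @param gene A `GeneRecord`.
#' @return A normalized `VariantQuery`.
#' @export
parse_variant_query <- function(text, gene) {
  text <- trimws(text)
  m <- regexec("^p\\.([A-Za-z])([0-9]+)([A-Za-z*])$", text)[[1L]]
  if (m[1L] != -1L) {
    g <- regmatches(text, list(m))[[1L]]
    return(variant_query(gene, prot_pos = as.integer(g[3L]),
                         ref_aa = toupper(g[2L]), alt_aa = toupper(g[4L]),
                         origin = "protein"))
  }
  m <- regexec("^c\\.([0-9]+)([ACGTacgt])>([ACGTacgt])$", text)[[1L]]
  if (m[1L] != -1L) {
    g <- regmatches(text, list(m))[[1L]]
    cds_pos <- as.integer(g[2L])
    ref_nt <- toupper(g[3L]); alt_nt <- toupper(g[4L])
    mp <- map_cds_to_protein(gene, cds_pos, ref_nt, alt_nt)
    return(variant_query(gene, prot_pos = mp$prot_pos,
                         ref_aa = mp$ref_aa, alt_aa = mp$alt_aa,
                         cds_pos = cds_pos, ref_nt = ref_nt, alt_nt = alt_nt,
                         origin = "cds"))
  }
  if (grepl("^[ACGTacgt]+$", text)) {
    if (nchar(text) < 100L) {
      stop("flanking sequence must be at least 100 nt for unique ",
           "identification (got ", nchar(text), ")", call. = FALSE)
    }
    flank <- toupper(text)
    cds_pos <- locate_flank(gene, flank)
    ref_nt <- substr(gene$cds_seq, cds_pos, cds_pos)
    alt_nt <- substr(flank, 1L, 1L)
    mp <- map_cds_to_protein(gene, cds_pos, ref_nt, alt_nt)
    return(variant_query(gene, prot_pos = mp$prot_pos,
                         ref_aa = mp$ref_aa, alt_aa = mp$alt_aa,
                         cds_pos = cds_pos, ref_nt = ref_nt, alt_nt = alt_nt,
                         origin = "flank"))
  }
  stop("unrecognized query format: '", text, "'", call. = FALSE)
}

#' Read a batch query table
#'
#' TSV with header columns `gene` and `query` (any format accepted by
#' [parse_variant_query()]).
#'
#' @param path TSV path.
#' @return data.frame with columns `gene`, `query`.
#' @export
read_batch <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(c("gene", "query"), names(df))
  if (length(miss)) {
    stop("batch file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}
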