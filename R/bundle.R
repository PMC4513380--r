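#' Load a per-gene resource directory
#'
#' Expected layout (written by [write_fixture_tree()] and accepted by the
#' CLI commands):
#' ```
#' dir/
#'   genes/<SYM>_protein.fasta      one record per file
#'   genes/<SYM>_cds.fasta
#'   alignments/<SYM>_protein_combined.fasta   (human row id "human")
#'   alignments/<SYM>_<kind>_<source>.fasta    optional report alignments,
#'       kind in {protein, nucleotide}, source in {ortholog, paralog}
#'   exons.tsv           gene, exon_index, length_nt
#'   known_variants.tsv  gene, prot_pos, ref_aa, alt_aa, classification, phenotype
#'   dataset.tsv         optional labeled evaluation dataset
#' ```
#'
#' @param dir Directory path.
#' @return List: `genes` (named `GeneRecord` list), `alignments` (named
#'   list of combined protein alignments), `report_alns` (per gene, named
#'   list of report alignments), `records` (known-variant data.frame),
#'   `dataset` (data.frame or NULL).
#' @export
load_gene_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  exons <- read_exons(file.path(dir, "exons.tsv"))
  prot_files <- list.files(file.path(dir, "genes"),
                           pattern = "_protein\\.fasta$", full.names = TRUE)
  genes <- list()
  for (pf in prot_files) {
    sym <- sub("_protein\\.fasta$", "", basename(pf))
    cf <- file.path(dir, "genes", paste0(sym, "_cds.fasta"))
    if (!file.exists(cf)) stop("missing CDS FASTA for ", sym, call. = FALSE)
    ex <- exons[[sym]]
    if (is.null(ex)) stop("missing exon rows for ", sym, call. = FALSE)
    genes[[sym]] <- gene_record(sym, read_fasta(pf)[[1L]],
                                read_fasta(cf)[[1L]], ex)
  }
  alignments <- list()
  report_alns <- list()
  for (sym in names(genes)) {
    comb <- file.path(dir, "alignments",
                      paste0(sym, "_protein_combined.fasta"))
    if (file.exists(comb)) {
      alignments[[sym]] <- read_alignment(comb, kind = "protein",
                                          source = "combined")
    }
    ra <- list()
    for (kind in c("protein", "nucleotide")) {
      for (src in c("ortholog", "paralog")) {
        f <- file.path(dir, "alignments",
                       paste0(sym, "_", kind, "_", src, ".fasta"))
        if (file.exists(f)) {
          ra[[paste0(kind, "_", src)]] <-
            read_alignment(f, kind = kind, source = src)
        }
      }
    }
    report_alns[[sym]] <- ra
  }
  kv <- file.path(dir, "known_variants.tsv")
  records <- if (file.exists(kv)) read_known_variants(kv) else
    data.frame(gene = character(0), prot_pos = integer(0),
               ref_aa = character(0), alt_aa = character(0),
               classification = character(0), phenotype = character(0),
               stringsAsFactors = FALSE)
  ds <- file.path(dir, "dataset.tsv")
  dataset <- if (file.exists(ds)) read.delim(ds, stringsAsFactors = FALSE)
             else NULL
  list(genes = genes, alignments = alignments, report_alns = report_alns,
       records = records, dataset = dataset)
}
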