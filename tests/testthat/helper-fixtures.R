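# Deterministic micro-fixtures shared across test files.

# Back-translate a protein deterministically (first synonymous codon,
# alphabetical) and append TAA, so tests control the CDS exactly.
codon_of <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- vapply(split(names(gc), unname(gc)), function(x) sort(x)[1L],
                character(1))
  function(aa) unname(tab[aa])
})

test_gene <- function(protein, exons = NULL, symbol = "TG1") {
  cds <- paste(c(vapply(strsplit(protein, "")[[1L]], codon_of, character(1)),
                 "TAA"), collapse = "")
  if (is.null(exons)) exons <- nchar(cds)
  gene_record(symbol, protein, cds, exons)
}

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}

# Alignment whose homolog rows at column `pos` carry a chosen composition:
# n_match copies of the human residue, the given mismatch residues, and
# n_gap gaps; all other columns copy the human row.
column_aln <- function(human_seq, pos, n_match = 0L, mismatches = character(0),
                       n_gap = 0L, kind = "protein") {
  chars <- strsplit(human_seq, "")[[1L]]
  h <- chars[pos]
  cells <- c(rep(h, n_match), mismatches, rep("-", n_gap))
  rows <- vapply(cells, function(ch) {
    r <- chars; r[pos] <- ch; paste(r, collapse = "")
  }, character(1))
  multiple_alignment(kind = kind,
                     ids = c("human", sprintf("hom%03d", seq_along(rows))),
                     seqs = c(human_seq, unname(rows)),
                     human_row_id = "human")
}

# Independent brute-force WPC oracle: direct column scan over the matrix.
wpc_oracle <- function(aln, pos) {
  col <- which(aln$matrix[aln$human_row_id, ] != "-")[pos]
  h <- aln$matrix[aln$human_row_id, col]
  a <- 0L; n <- 0L
  for (id in aln$ids) {
    if (id == aln$human_row_id) next
    ch <- aln$matrix[id, col]
    if (ch == "-") next
    n <- n + 1L
    if (ch == h) a <- a + 1L
  }
  if (n == 0L) return(NA_real_)
  100 * a / n
}

# Independent Mann-Whitney AUC oracle (pairwise comparisons with ties).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

small_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[[1L]], prot_pos = as.integer(r[[2L]]),
               ref_aa = r[[3L]], alt_aa = r[[4L]],
               classification = r[[5L]], phenotype = r[[6L]],
               stringsAsFactors = FALSE)
  }))
}
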