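with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

REV_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Fixture specification for the synthetic generators
#'
#' Defaults describe the benchmark conditions used throughout the test
#' suite: 100 genes of 400 residues, combined ortholog+paralog alignments
#' of 30 homologs with 5 percent independent gap rate, per-column
#' conservation drawn uniformly on `[0, 1]`, two disjoint hotspot regions
#' per gene with distinct phenotypes, 20 evaluation variants per gene
#' (2000 total) labeled pathogenic at a WPC of 55 or above.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of genes.
#' @param protein_length Protein length (residues).
#' @param n_homologs Non-human rows per combined alignment.
#' @param gap_rate Independent per-cell gap probability in homolog rows.
#' @param conservation_profile Numeric vector of per-column target match
#'   probabilities (length `protein_length`), or `NULL` to draw uniformly
#'   per gene.
#' @param hotspot_regions List of `list(start, end, phenotype)` regions, or
#'   `NULL` for the default two-region layout scaled to `protein_length`.
#' @param n_variants Total evaluation variants across all genes.
#' @param n_known_per_region Pathogenic known-variant records planted per
#'   hotspot region per gene.
#' @param n_benign_known Benign known-variant records scattered per gene.
#' @param pathogenic_rule WPC percent threshold defining the generative
#'   truth label (`wpc-only` mode), or `list(psic, wpc)` for the
#'   two-feature rule.
#' @return List of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 100L, protein_length = 400L,
                         n_homologs = 30L, gap_rate = 0.05,
                         conservation_profile = NULL,
                         hotspot_regions = NULL,
                         n_variants = 2000L,
                         n_known_per_region = 25L,
                         n_benign_known = 15L,
                         pathogenic_rule = 55) {
  if (is.null(hotspot_regions)) {
    L <- protein_length
    hotspot_regions <- list(
      list(start = max(1L, round(0.05 * L)), end = round(0.45 * L),
           phenotype = "DiseaseA"),
      list(start = round(0.55 * L), end = round(0.95 * L),
           phenotype = "DiseaseB"))
  }
  for (r in hotspot_regions) {
    if (r$start < 1L || r$end > protein_length || r$start > r$end) {
      stop("hotspot region outside protein", call. = FALSE)
    }
  }
  if (!is.null(conservation_profile)) {
    stopifnot(length(conservation_profile) == protein_length,
              all(conservation_profile >= 0 & conservation_profile <= 1))
  }
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         protein_length = as.integer(protein_length),
         n_homologs = as.integer(n_homologs), gap_rate = gap_rate,
         conservation_profile = conservation_profile,
         hotspot_regions = hotspot_regions,
         n_variants = as.integer(n_variants),
         n_known_per_region = as.integer(n_known_per_region),
         n_benign_known = as.integer(n_benign_known),
         pathogenic_rule = pathogenic_rule),
    class = "FixtureSpec"
  )
}

#' Generate a random but internally consistent gene record
#'
#' The protein starts with methionine; each residue is back-translated
#' through a uniformly chosen synonymous codon and a random stop codon is
#' appended, so the CDS always satisfies the gene-record invariants. Exon
#' lengths are a random composition of the CDS length into 2-8 parts.
#'
#' @param spec A `FixtureSpec` (supplies `protein_length`).
#' @param seed Integer seed; the generator is bit-reproducible per seed.
#' @param symbol Gene symbol (default derived from the seed).
#' @return A `GeneRecord`.
#' @export
make_gene <- function(spec, seed, symbol = sprintf("GENE%04d", seed %% 10000L)) {
  with_seed(seed, {
    L <- spec$protein_length
    protein <- paste(c("M", sample(AA_LETTERS, L - 1L, replace = TRUE)),
                     collapse = "")
    aa <- seq_chars(protein)
    codons <- vapply(aa, function(a) sample(REV_CODON[[a]], 1L), character(1))
    cds <- paste(c(codons, sample(REV_CODON[["*"]], 1L)), collapse = "")
    n_ex <- sample(2:8, 1L)
    cuts <- sort(sample(seq_len(nchar(cds) - 1L), n_ex - 1L))
    exons <- diff(c(0L, cuts, nchar(cds)))
    gene_record(symbol, protein, cds, exons)
  })
}

#' Generate a homolog alignment with controlled per-column conservation
#'
#' Each homolog cell is gapped with probability `gap_rate`; otherwise it
#' matches the human character with the column's target probability and is
#' a uniformly drawn different character otherwise. The human row (id
#' `"human"`) is the ungapped gene sequence, so alignment columns coincide
#' with reference positions.
#'
#' @param gene A `GeneRecord`.
#' @param n_homologs Number of non-human rows.
#' @param conservation_profile Per-column match probabilities; length must
#'   equal the protein length (protein kind) or CDS length (nucleotide
#'   kind; a protein-length profile is expanded codon-wise).
#' @param seed Integer seed.
#' @param kind `"protein"` or `"nucleotide"`.
#' @param gap_rate Per-cell gap probability (default 0.05).
#' @param source Alignment provenance label (default `"combined"`).
#' @return A `MultipleAlignment`.
#' @export
make_homolog_alignment <- function(gene, n_homologs, conservation_profile,
                                   seed, kind = c("protein", "nucleotide"),
                                   gap_rate = 0.05,
                                   source = "combined") {
  kind <- match.arg(kind)
  human <- if (kind == "protein") gene$protein_seq else gene$cds_seq
  L <- nchar(human)
  if (kind == "nucleotide" &&
      length(conservation_profile) == nchar(gene$protein_seq)) {
    conservation_profile <- c(rep(conservation_profile, each = 3L),
                              rep(1, L - 3L * nchar(gene$protein_seq)))
  }
  stopifnot(length(conservation_profile) == L)
  alphabet <- if (kind == "protein") AA_LETTERS else NT_LETTERS
  A <- length(alphabet)
  hchars <- seq_chars(human)
  hidx <- match(hchars, alphabet)
  with_seed(seed, {
    # Columns vary among a small set of exchangeable characters, as in real
    # alignments: each column gets two fixed non-human alternatives and
    # mismatching cells draw uniformly between them.
    alt_of <- function() {
      r <- sample.int(A - 1L, L, replace = TRUE)
      alphabet[r + (r >= hidx)]
    }
    alt1 <- alt_of()
    alt2 <- alt_of()
    swap <- alt2 == alt1  # keep the two alternatives distinct
    alt2[swap] <- alphabet[1L + (match(alt1[swap], alphabet) %% A)]
    alt2[swap][alt2[swap] == hchars[swap]] <-
      alphabet[1L + (match(alt2[swap][alt2[swap] == hchars[swap]],
                           alphabet) %% A)]
    rows <- vapply(seq_len(n_homologs), function(i) {
      match <- runif(L) < conservation_profile
      pick <- runif(L) < 0.5
      out <- ifelse(match, hchars, ifelse(pick, alt1, alt2))
      out[runif(L) < gap_rate] <- "-"
      paste(out, collapse = "")
    }, character(1))
    multiple_alignment(kind = kind,
                       ids = c("human", sprintf("hom%03d", seq_len(n_homologs))),
                       seqs = c(human, rows),
                       human_row_id = "human", source = source)
  })
}

#' Generate a known-variant catalogue and a labeled evaluation dataset
#'
#' For every gene: pathogenic known-variant records are planted uniformly
#' inside each hotspot region carrying the region's phenotype, and benign
#' records are scattered over the whole protein. Evaluation variants are
#' drawn inside hotspot regions (so the literature layer marks them all as
#' hotspot members) with a random non-reference alternate residue; each is
#' scored against the gene's combined alignment and its truth label is
#' pathogenic when the realized conservation meets the generative rule
#' (`wpc >= pathogenic_rule`, or `psic >= rule$psic & wpc >= rule$wpc` for
#' the two-feature rule).
#'
#' @param genes Named list of `GeneRecord`s.
#' @param alignments Named list of combined protein alignments (same names).
#' @param spec A `FixtureSpec`.
#' @param seed Integer seed.
#' @return List: `known` (known-variant data.frame), `dataset` (evaluation
#'   data.frame with `gene`, `prot_pos`, `ref_aa`, `alt_aa`, `wpc`, `psic`,
#'   `hotspot`, `truth_label`).
#' @export
make_variant_catalogue <- function(genes, alignments, spec, seed) {
  with_seed(seed, {
    known <- list()
    dataset <- list()
    per_gene <- ceiling(spec$n_variants / length(genes))
    rule <- spec$pathogenic_rule
    for (sym in names(genes)) {
      gene <- genes[[sym]]
      aln <- alignments[[sym]]
      prof <- psic_profile(aln)
      prot <- seq_chars(gene$protein_seq)
      for (r in spec$hotspot_regions) {
        pos <- sample(r$start:r$end, spec$n_known_per_region, replace = TRUE)
        known[[length(known) + 1L]] <- data.frame(
          gene = sym, prot_pos = pos, ref_aa = prot[pos],
          alt_aa = vapply(prot[pos], function(a)
            sample(setdiff(AA_LETTERS, a), 1L), character(1)),
          classification = "pathogenic", phenotype = r$phenotype,
          stringsAsFactors = FALSE)
      }
      pos <- sample.int(length(prot), spec$n_benign_known, replace = TRUE)
      known[[length(known) + 1L]] <- data.frame(
        gene = sym, prot_pos = pos, ref_aa = prot[pos],
        alt_aa = vapply(prot[pos], function(a)
          sample(setdiff(AA_LETTERS, a), 1L), character(1)),
        classification = "benign", phenotype = "",
        stringsAsFactors = FALSE)
      region_pool <- unlist(lapply(spec$hotspot_regions,
                                   function(r) r$start:r$end))
      vpos <- sample(region_pool, per_gene, replace = TRUE)
      # Half the alternate residues are substitutions actually observed in
      # the homolog column (tolerated exchanges, low PSIC contrast), half
      # are novel; catalogues thus span both conservation axes instead of
      # tying PSIC to WPC.
      hom_rows <- setdiff(aln$ids, aln$human_row_id)
      valt <- vapply(seq_along(vpos), function(i) {
        p <- vpos[i]
        col <- aln$matrix[hom_rows, aln$colmap[p]]
        seen <- col[col != "-" & col != prot[p] & col %in% AA_LETTERS]
        if (length(seen) && runif(1) < 0.5) sample(seen, 1L)
        else sample(setdiff(AA_LETTERS, prot[p]), 1L)
      }, character(1))
      wpc <- vapply(vpos, function(p) wpc_score(aln, p, prot[p]), numeric(1))
      psic <- vapply(seq_along(vpos), function(i)
        psic_delta(prof, vpos[i], prot[vpos[i]], valt[i]), numeric(1))
      truth <- if (is.list(rule)) {
        psic >= rule$psic & wpc >= rule$wpc
      } else {
        wpc >= rule
      }
      dataset[[length(dataset) + 1L]] <- data.frame(
        gene = sym, prot_pos = vpos, ref_aa = prot[vpos], alt_aa = valt,
        wpc = wpc, psic = psic, hotspot = TRUE,
        truth_label = ifelse(truth, "pathogenic", "benign"),
        stringsAsFactors = FALSE)
    }
    dataset <- do.call(rbind, dataset)
    if (nrow(dataset) > spec$n_variants) {
      dataset <- dataset[seq_len(spec$n_variants), , drop = FALSE]
    }
    known <- do.call(rbind, known)
    rownames(known) <- NULL
    rownames(dataset) <- NULL
    list(known = known, dataset = dataset)
  })
}

#' Generate a full fixture: genes, alignments, catalogue
#'
#' Convenience wrapper deriving per-gene seeds from the master seed.
#'
#' @param spec A `FixtureSpec`.
#' @return List: `genes`, `alignments` (combined protein), `profiles`
#'   (per-gene conservation profiles actually used), `known`, `dataset`,
#'   `spec`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  base <- spec$seed %% 100000L
  genes <- list()
  alignments <- list()
  profiles <- list()
  for (i in seq_len(spec$n_genes)) {
    sym <- sprintf("GENE%04d", i)
    genes[[sym]] <- make_gene(spec, seed = base + 7L * i, symbol = sym)
    prof <- if (is.null(spec$conservation_profile)) {
      with_seed(base + 7L * i + 3L, runif(spec$protein_length))
    } else spec$conservation_profile
    profiles[[sym]] <- prof
    alignments[[sym]] <- make_homolog_alignment(
      genes[[sym]], spec$n_homologs, prof, seed = base + 7L * i + 5L,
      kind = "protein", gap_rate = spec$gap_rate)
  }
  cat_seed <- base + 900001L
  catalogue <- make_variant_catalogue(genes, alignments, spec, cat_seed)
  list(genes = genes, alignments = alignments, profiles = profiles,
       known = catalogue$known, dataset = catalogue$dataset, spec = spec)
}

#' Write a fixture as a loadable gene-resource directory
#'
#' Writes the exact dialects the readers consume; the result round-trips
#' through [load_gene_bundle()].
#'
#' @param fixture Result of [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_tree <- function(fixture, dir) {
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  exon_rows <- list()
  for (sym in names(fixture$genes)) {
    g <- fixture$genes[[sym]]
    write_fasta(setNames(list(g$protein_seq), sym),
                file.path(dir, "genes", paste0(sym, "_protein.fasta")))
    write_fasta(setNames(list(g$cds_seq), sym),
                file.path(dir, "genes", paste0(sym, "_cds.fasta")))
    write_alignment(fixture$alignments[[sym]],
                    file.path(dir, "alignments",
                              paste0(sym, "_protein_combined.fasta")))
    exon_rows[[sym]] <- data.frame(gene = sym,
                                   exon_index = seq_along(g$exons),
                                   length_nt = g$exons)
  }
  write.table(do.call(rbind, exon_rows), file.path(dir, "exons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_known_variants(fixture$known, file.path(dir, "known_variants.tsv"))
  write.table(fixture$dataset, file.path(dir, "dataset.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
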