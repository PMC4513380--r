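test_that("WPC counts matching homologs over valid rows", {
  human <- "MKTWAEDNRS"
  expect_equal(wpc_score(column_aln(human, 4, n_match = 10), 4, "W"), 100)
  expect_equal(wpc_score(column_aln(human, 4,
                                    mismatches = rep("A", 10)), 4, "W"), 0)
  # 8 valid homolog rows, 3 matching, 2 gapped rows excluded
  a <- column_aln(human, 4, n_match = 3, mismatches = rep("G", 5), n_gap = 2)
  st <- column_stats(a, 4, "W")
  expect_equal(st$a_i, 3L)
  expect_equal(st$n_h, 8L)
  expect_equal(st$wpc, 37.5)
  # all homologs gapped -> undefined score error
  expect_error(wpc_score(column_aln(human, 4, n_gap = 5), 4, "W"),
               class = "snpcons_undefined_wpc")
  # reference mismatch against the human row is a consistency error
  expect_error(wpc_score(a, 4, "A"), "query reference")
})

test_that("WPC equals the brute-force column scan on random fixtures", {
  set.seed(101)
  for (i in 1:50) {
    human <- random_protein(30)
    n_hom <- sample(3:20, 1)
    pos <- sample(30, 1)
    h <- substr(human, pos, pos)
    cells <- sample(c(h, "A", "G", "-", substr(random_protein(1), 1, 1)),
                    n_hom, replace = TRUE)
    a <- tryCatch(column_aln(human, pos,
                             n_match = sum(cells == h),
                             mismatches = cells[cells != h & cells != "-"],
                             n_gap = sum(cells == "-")),
                  error = function(e) NULL)
    if (is.null(a)) next
    oracle <- wpc_oracle(a, pos)
    if (is.na(oracle)) {
      expect_error(wpc_score(a, pos, h), class = "snpcons_undefined_wpc")
    } else {
      expect_equal(wpc_score(a, pos, h), oracle)
    }
  }
})

test_that("WPC is invariant to row order and fully-gapped rows, monotone in evidence", {
  human <- "MKTWAEDNRS"
  a <- column_aln(human, 6, n_match = 4, mismatches = c("G", "V", "L"))
  base <- wpc_score(a, 6, "E")
  # permute rows
  perm <- sample(length(a$ids))
  ap <- multiple_alignment("protein", a$ids[perm],
                           apply(a$matrix[perm, ], 1, paste, collapse = ""),
                           "human")
  expect_equal(wpc_score(ap, 6, "E"), base)
  # append a fully-gapped row
  ag <- multiple_alignment("protein", c(a$ids, "gapped"),
                           c(apply(a$matrix, 1, paste, collapse = ""),
                             paste(rep("-", 10), collapse = "")), "human")
  expect_equal(wpc_score(ag, 6, "E"), base)
  # one more matching row never decreases WPC; a mismatch never increases it
  am <- column_aln(human, 6, n_match = 5, mismatches = c("G", "V", "L"))
  expect_gte(wpc_score(am, 6, "E"), base)
  ax <- column_aln(human, 6, n_match = 4, mismatches = c("G", "V", "L", "P"))
  expect_lte(wpc_score(ax, 6, "E"), base)
})

test_that("percent conservation works on nucleotide alignments and matches WPC", {
  cds <- "ATGAAAACCTGG"
  expect_equal(percent_conservation(
    column_aln(cds, 5, n_match = 6, kind = "nucleotide"), 5), 100)
  expect_equal(percent_conservation(
    column_aln(cds, 5, n_match = 1, mismatches = c("C", "G", "T"),
               kind = "nucleotide"), 5), 25)
  a <- column_aln("MKTWAEDNRS", 3, n_match = 2, mismatches = c("A", "G"))
  expect_equal(percent_conservation(a, 3), wpc_score(a, 3, "T"))
})

test_that("PSIC profile ranks observed residues and is duplication-invariant", {
  set.seed(31)
  human <- random_protein(25)
  rows <- vapply(1:12, function(i) random_protein(25), character(1))
  substr(rows[1], 3, 3)
  # make column 3 all-alanine across every row
  human3 <- human; substr(human3, 3, 3) <- "A"
  rows <- vapply(rows, function(r) { substr(r, 3, 3) <- "A"; r }, character(1))
  a <- multiple_alignment("protein", c("human", sprintf("h%02d", 1:12)),
                          c(human3, unname(rows)), "human")
  prof <- psic_profile(a)
  col3 <- a$colmap[3]
  expect_equal(names(which.max(prof$values[, col3])), "A")
  # duplicating an existing row leaves the profile unchanged (< 1e-6)
  a2 <- multiple_alignment("protein", c(a$ids, "dup"),
                           c(apply(a$matrix, 1, paste, collapse = ""),
                             rows[[5]]), "human")
  expect_lt(max(abs(psic_profile(a2)$values - prof$values)), 1e-6)
  expect_true(all(is.finite(prof$values)))
})

test_that("a uniform column yields near-equal profile values", {
  set.seed(41)
  human <- random_protein(10)
  # 20 homolog rows, each residue represented exactly once at column 4
  rows <- vapply(seq_along(c("A","C","D","E","F","G","H","I","K","L",
                             "M","N","P","Q","R","S","T","V","W","Y")),
                 function(i) {
    r <- random_protein(10)
    substr(r, 4, 4) <- c("A","C","D","E","F","G","H","I","K","L",
                         "M","N","P","Q","R","S","T","V","W","Y")[i]
    r
  }, character(1))
  human4 <- human; substr(human4, 4, 4) <- "A"
  a <- multiple_alignment("protein", c("human", sprintf("h%02d", 1:20)),
                          c(human4, rows), "human")
  prof <- psic_profile(a)
  vals <- prof$values[, a$colmap[4]]
  # column holds 21 observations: each residue once, A twice (human row)
  expect_lt(max(vals[names(vals) != "A"]) - min(vals[names(vals) != "A"]),
            1e-12)
})

test_that("PSIC delta is symmetric, zero at identity, and large for deep conservation", {
  set.seed(51)
  human <- random_protein(30)
  rows <- vapply(1:30, function(i) random_protein(30), character(1))
  h7 <- substr(human, 7, 7)
  rows <- vapply(rows, function(r) { substr(r, 7, 7) <- h7; r }, character(1))
  a <- multiple_alignment("protein", c("human", sprintf("h%02d", 1:30)),
                          c(human, unname(rows)), "human")
  prof <- psic_profile(a)
  expect_equal(psic_delta(prof, 7, h7, h7), 0)
  alt <- setdiff(c("A", "W"), h7)[1L]
  d <- psic_delta(prof, 7, h7, alt)
  expect_equal(d, psic_delta(prof, 7, alt, h7))
  # closed form with 31 independent ungapped rows, pseudocount 1:
  # log(20*32/51) - log(20*1/51) = log(32)
  expect_equal(d, log(32), tolerance = 1e-12)
  expect_gt(d, 1.03)
  expect_error(psic_delta(prof, 7, h7, "*"), "not scored")
})

test_that("BLOSUM62 lookups match the published matrix", {
  expect_equal(blosum62("W", "W"), 11L)
  expect_equal(blosum62("A", "A"), 4L)
  expect_error(blosum62("A", "1"), "unknown")
  aas <- rownames(snpcons:::load_blosum62())
  m <- outer(aas, aas, blosum62)
  expect_equal(m, t(m))
  # independent copy shipped with Biostrings
  data("BLOSUM62", package = "Biostrings", envir = environment())
  ref <- get("BLOSUM62", envir = environment())
  common <- intersect(rownames(ref), aas)
  expect_equal(outer(common, common, blosum62),
               unname(ref[common, common]))
})

test_that("conservation reports fill protein columns and respect codon ambiguity", {
  g <- gene_record("TG2", "MLKTWAEDNRSY",
                   "ATGTTAAAAACCTGGGCAGAAGATAATCGAAGTTATTAA", 39L)
  aln <- column_aln(g$protein_seq, 2, n_match = 4, mismatches = "A")
  orth <- column_aln(g$protein_seq, 2, n_match = 2, mismatches = c("A", "G"))
  nt_orth <- column_aln(g$cds_seq, 6, n_match = 3, kind = "nucleotide")
  recs <- small_records(list("TG2", 5, "W", "R", "pathogenic", "DiseaseX"))
  # L2F maps ambiguously (TTC/TTT) -> nucleotide columns suppressed
  q <- parse_variant_query("p.L2F", g)
  rep1 <- conservation_report(q, g, aln,
                              list(protein_ortholog = orth,
                                   nucleotide_ortholog = nt_orth),
                              recs)
  expect_equal(rep1$wpc, 80)
  expect_equal(rep1$pct_protein_ortholog, 50)
  expect_true(is.na(rep1$pct_nucleotide_ortholog))
  expect_true(rep1$ambiguous_codon)
  expect_equal(rep1$known_in_window, 1L)
  # unambiguous variant (K3E via A7G) fills the nucleotide column
  q2 <- parse_variant_query("p.K3E", g)
  rep2 <- conservation_report(q2, g, aln,
                              list(nucleotide_ortholog = nt_orth), recs)
  expect_false(rep2$ambiguous_codon)
  expect_equal(rep2$pct_nucleotide_ortholog, 100)
  expect_equal(rep2$blosum62, blosum62("K", "E"))
})
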