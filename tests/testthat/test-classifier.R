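# Independent oracle implementing the ordered decision rules directly on
# precomputed evidence, used to cross-check classify_variant branch by branch.
rules_oracle <- function(stop_gain_ok, hotspot, wpc, psic, config) {
  if (stop_gain_ok && config$use_stopgain) return("Pathogenic")
  if (config$use_hotspot && !hotspot) return("Benign(h)")
  if (config$use_psic && !is.na(psic) && psic < config$psic_cutoff) {
    return("Benign(a)")
  }
  cutoff <- if (config$use_psic) config$wpc_cutoff_with_psic
            else config$wpc_cutoff_default
  if (wpc >= cutoff) "Pathogenic" else "Benign(a)"
}

test_that("genes without nearby disease literature are Benign(h)", {
  g <- test_gene(random_protein(50))
  aln <- column_aln(g$protein_seq, 10, n_match = 8)
  empty <- small_records(list("OTHER", 5, "A", "V", "pathogenic", "D"))
  r <- classify_variant(paste0("p.", substr(g$protein_seq, 10, 10), "10A"),
                        g, aln, empty, pipeline_config())
  expect_equal(r$label, "Benign(h)")
  expect_equal(r$reason, "no_hotspot")
  expect_false(r$hotspot)
  expect_equal(r$phenotype$status, "no_data")
})

test_that("WPC boundary behaviour matches the printed cutoffs exactly", {
  set.seed(81)
  g <- test_gene(random_protein(50))
  h <- substr(g$protein_seq, 10, 10)
  recs <- small_records(list(g$symbol, 30, "A", "V", "pathogenic", "DiseaseX"))
  recs$ref_aa <- substr(g$protein_seq, 30, 30)
  # 49 of 100 homologs match -> WPC exactly 49 -> Pathogenic at default cutoff
  a49 <- column_aln(g$protein_seq, 10, n_match = 49,
                    mismatches = rep("A", 51))
  r <- classify_variant(paste0("p.", h, "10G"), g, a49, recs,
                        pipeline_config())
  expect_equal(r$wpc, 49)
  expect_equal(r$label, "Pathogenic")
  expect_equal(r$reason, "wpc_high")
  # 489 of 1000 -> WPC 48.9 -> Benign(a)
  a489 <- column_aln(g$protein_seq, 10, n_match = 489,
                     mismatches = rep("A", 511))
  r2 <- classify_variant(paste0("p.", h, "10G"), g, a489, recs,
                         pipeline_config())
  expect_equal(r2$wpc, 48.9)
  expect_equal(r2$label, "Benign(a)")
  expect_equal(r2$reason, "wpc_low")
  # with the PSIC filter on, the operative WPC cutoff drops to 40
  a40 <- column_aln(g$protein_seq, 10, n_match = 40,
                    mismatches = rep("A", 60))
  cfg_psic <- pipeline_config(use_psic = TRUE, psic_cutoff = 0)
  r3 <- classify_variant(paste0("p.", h, "10G"), g, a40, recs, cfg_psic)
  expect_equal(r3$wpc, 40)
  expect_equal(r3$label, "Pathogenic")
})

test_that("a low PSIC score short-circuits to Benign(a) before the WPC step", {
  set.seed(82)
  g <- test_gene(random_protein(50))
  h <- substr(g$protein_seq, 10, 10)
  recs <- small_records(list(g$symbol, 30,
                             substr(g$protein_seq, 30, 30), "V",
                             "pathogenic", "DiseaseX"))
  aln <- column_aln(g$protein_seq, 10, n_match = 20)  # WPC 100
  prof <- psic_profile(aln)
  alt <- setdiff(c("A", "G"), h)[1L]
  d <- psic_delta(prof, 10, h, alt)
  q <- paste0("p.", h, "10", alt)
  # cutoff just above the computed delta -> psic_low despite WPC 100
  r <- classify_variant(q, g, aln, recs,
                        pipeline_config(use_psic = TRUE,
                                        psic_cutoff = d + 1e-9))
  expect_equal(r$label, "Benign(a)")
  expect_equal(r$reason, "psic_low")
  # boundary: delta == cutoff is NOT below -> falls through to WPC
  r2 <- classify_variant(q, g, aln, recs,
                         pipeline_config(use_psic = TRUE, psic_cutoff = d))
  expect_equal(r2$label, "Pathogenic")
  expect_equal(r2$reason, "wpc_high")
})

test_that("qualifying stop-gains are pathogenic regardless of conservation", {
  set.seed(83)
  # junction at 240; codon of position 40 starts at 118 -> 122 nt upstream
  g <- test_gene(random_protein(99), exons = c(120, 120, 60))
  h <- substr(g$protein_seq, 40, 40)
  aln <- column_aln(g$protein_seq, 40, n_match = 1, mismatches = rep("A", 19))
  r <- classify_variant(paste0("p.", h, "40*"), g, aln,
                        small_records(list("NONE", 1, "M", "V", "benign", "")),
                        pipeline_config())
  expect_equal(r$label, "Pathogenic")
  expect_equal(r$reason, "stop_gain")
  expect_true(r$stop_gain)
  # a stop in the final exon falls through; with no hotspot it is Benign(h)
  h90 <- substr(g$protein_seq, 90, 90)
  r2 <- classify_variant(paste0("p.", h90, "90*"), g, aln,
                         small_records(list("NONE", 1, "M", "V", "benign", "")),
                         pipeline_config())
  expect_equal(r2$label, "Benign(h)")
  # ... and with a hotspot it is decided by WPC computed against the ref residue
  recs <- small_records(list(g$symbol, 80, substr(g$protein_seq, 80, 80),
                             "V", "pathogenic", "DiseaseX"))
  aln90 <- column_aln(g$protein_seq, 90, n_match = 9, mismatches = "A")
  r3 <- classify_variant(paste0("p.", h90, "90*"), g, aln90, recs,
                         pipeline_config())
  expect_equal(r3$wpc, 90)
  expect_equal(r3$label, "Pathogenic")
  expect_equal(r3$reason, "wpc_high")
  # stop-gain assessment can be disabled for benchmarking parity
  r4 <- classify_variant(paste0("p.", h, "40*"), g, aln,
                         small_records(list("NONE", 1, "M", "V", "benign", "")),
                         pipeline_config(use_stopgain = FALSE))
  expect_equal(r4$label, "Benign(h)")
})

test_that("every branch combination matches the ordered-rules oracle", {
  set.seed(84)
  g <- test_gene(random_protein(99), exons = c(120, 120, 60))
  recs_hot <- small_records(list(g$symbol, 45, substr(g$protein_seq, 45, 45),
                                 "V", "pathogenic", "DiseaseX"))
  recs_cold <- small_records(list("OTHER", 45, "A", "V", "pathogenic", "D"))
  pos_ng <- 40L   # qualifying stop-gain position (122 nt upstream of junction)
  pos_fe <- 90L   # final-exon position (stop-gain falls through)
  for (wpc_target in c(10, 39, 40, 41, 48, 49, 50, 95)) {
    for (pos in c(pos_ng, pos_fe)) {
      h <- substr(g$protein_seq, pos, pos)
      aln <- column_aln(g$protein_seq, pos, n_match = wpc_target,
                        mismatches = rep("A", 100 - wpc_target))
      prof <- psic_profile(aln)
      for (alt in c("G", "*")) {
        if (alt == h) next
        psic <- if (alt == "*") NA_real_ else psic_delta(prof, pos, h, alt)
        for (use_psic in c(FALSE, TRUE)) {
          for (psic_cut in if (use_psic && !is.na(psic))
                             c(psic - 0.01, psic, psic + 0.01) else 1.03) {
            for (use_hot in c(FALSE, TRUE)) {
              for (recs in list(recs_hot, recs_cold)) {
                cfg <- pipeline_config(use_psic = use_psic,
                                       use_hotspot = use_hot,
                                       psic_cutoff = psic_cut)
                hotspot <- in_functional_hotspot(recs, g$symbol, pos,
                                                 cfg$range_aa, h, alt)
                stop_ok <- alt == "*" && pos == pos_ng
                want <- rules_oracle(stop_ok, hotspot, wpc_target, psic, cfg)
                got <- classify_variant(paste0("p.", h, pos, alt), g, aln,
                                        recs, cfg, profile = prof)
                expect_equal(got$label, want,
                             info = sprintf("wpc=%s pos=%s alt=%s psic=%s cut=%s hot=%s",
                                            wpc_target, pos, alt, use_psic,
                                            psic_cut, use_hot))
              }
            }
          }
        }
      }
    }
  }
})

test_that("raising the WPC cutoff never converts Benign to Pathogenic", {
  set.seed(85)
  g <- test_gene(random_protein(50))
  h <- substr(g$protein_seq, 25, 25)
  recs <- small_records(list(g$symbol, 30, substr(g$protein_seq, 30, 30),
                             "V", "pathogenic", "DiseaseX"))
  for (nm in c(5, 13, 27)) {
    aln <- column_aln(g$protein_seq, 25, n_match = nm,
                      mismatches = rep("A", 30 - nm))
    prev_path <- TRUE
    for (cut in seq(0, 100, by = 10)) {
      r <- classify_variant(paste0("p.", h, "25G"), g, aln, recs,
                            pipeline_config(wpc_cutoff_default = cut))
      path <- r$label == "Pathogenic"
      expect_false(!prev_path && path)  # benign never flips back
      prev_path <- path
    }
  }
})

test_that("undefined WPC surfaces as a classification error with evidence", {
  g <- test_gene(random_protein(30))
  h <- substr(g$protein_seq, 5, 5)
  aln <- column_aln(g$protein_seq, 5, n_gap = 6)
  recs <- small_records(list(g$symbol, 10, substr(g$protein_seq, 10, 10),
                             "V", "pathogenic", "DiseaseX"))
  err <- tryCatch(classify_variant(paste0("p.", h, "5A"), g, aln, recs,
                                   pipeline_config()),
                  snpcons_classification_error = function(e) e)
  expect_s3_class(err, "snpcons_classification_error")
  expect_true(err$evidence$hotspot)
})

test_that("batch classification equals per-query classification and isolates row errors", {
  spec <- fixture_spec(seed = 99, n_genes = 2, protein_length = 120,
                       n_homologs = 12, n_variants = 10,
                       n_known_per_region = 5, n_benign_known = 3)
  fx <- make_fixture(spec)
  dir <- withr::local_tempdir()
  write_fixture_tree(fx, dir)
  bundle <- load_gene_bundle(dir)
  qs <- fx$dataset[1:5, ]
  batch <- data.frame(gene = qs$gene,
                      query = paste0("p.", qs$ref_aa, qs$prot_pos, qs$alt_aa),
                      stringsAsFactors = FALSE)
  out <- classify_batch(batch, bundle, pipeline_config())
  expect_equal(length(out$results), 5L)
  expect_equal(nrow(out$errors), 0L)
  for (i in 1:5) {
    single <- classify_variant(batch$query[i], bundle$genes[[batch$gene[i]]],
                               bundle$alignments[[batch$gene[i]]],
                               bundle$records, pipeline_config())
    expect_equal(out$results[[i]]$label, single$label)
    expect_equal(out$results[[i]]$wpc, single$wpc)
  }
  # one malformed row among five is reported, not fatal
  batch$query[3] <- "p.Z9999Q"
  out2 <- classify_batch(batch, bundle, pipeline_config())
  expect_equal(length(out2$results), 4L)
  expect_equal(out2$errors$row, 3L)
})

test_that("with hotspot screening off no Benign(h) is produced and phenotype is no_data", {
  spec <- fixture_spec(seed = 77, n_genes = 1, protein_length = 150,
                       n_homologs = 10, n_variants = 12,
                       n_known_per_region = 4, n_benign_known = 2)
  fx <- make_fixture(spec)
  cfg <- pipeline_config(use_hotspot = FALSE)
  g <- fx$genes[[1]]; aln <- fx$alignments[[1]]
  for (i in seq_len(nrow(fx$dataset))) {
    v <- fx$dataset[i, ]
    r <- classify_variant(paste0("p.", v$ref_aa, v$prot_pos, v$alt_aa),
                          g, aln, fx$known, cfg)
    expect_false(r$label == "Benign(h)")
    expect_equal(r$phenotype$status, "no_data")
  }
})
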