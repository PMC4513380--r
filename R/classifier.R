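#' Classify one variant with the stepwise pipeline
#'
#' Ordered decision rules:
#' 1. A stop-gain satisfying the nonsense-mediated-decay distance rule is
#'    `Pathogenic` (reason `stop_gain`); other stop-gains fall through.
#' 2. With hotspot screening on, a variant outside any functional hotspot
#'    is `Benign(h)` (reason `no_hotspot`).
#' 3. With the PSIC filter on, a substitution score strictly below
#'    `psic_cutoff` is `Benign(a)` (reason `psic_low`). Stop-gains that
#'    fell through step 1 skip this step (the profile does not score `*`).
#' 4. WPC at or above the operative cutoff (`wpc_cutoff_with_psic` when the
#'    PSIC filter is on, else `wpc_cutoff_default`) is `Pathogenic`
#'    (reason `wpc_high`); below is `Benign(a)` (reason `wpc_low`). For a
#'    fallen-through stop-gain WPC is computed against the reference
#'    residue (`*` never matches a column).
#'
#' A phenotype prediction is attached whenever hotspot screening is on;
#' with it off the phenotype status is `no_data`.
#'
#' @param query A `VariantQuery` (or query text parsed against `gene`).
#' @param gene A `GeneRecord`.
#' @param combined_aln Combined ortholog+paralog protein alignment.
#' @param records Known-variant data.frame.
#' @param config A `PipelineConfig`.
#' @param profile Optional precomputed `PsicProfile` of `combined_aln`.
#' @return Object of class `ClassificationResult`.
#' @export
classify_variant <- function(query, gene, combined_aln, records,
                             config = pipeline_config(), profile = NULL) {
  if (is.character(query)) query <- parse_variant_query(query, gene)
  stopifnot(inherits(query, "VariantQuery"))
  evidence <- list(query = query, label = NA_character_,
                   reason = NA_character_, wpc = NA_real_, psic = NA_real_,
                   hotspot = NA, stop_gain = FALSE,
                   phenotype = structure(
                     list(status = "no_data", phenotype = "", support = 0L,
                          total_in_window = 0L,
                          nearest_distance = NA_integer_),
                     class = "PhenotypePrediction"))

  # (1) stop-gain / NMD rule
  if (query$alt_aa == "*" && config$use_stopgain) {
    mapping <- map_protein_to_cds(gene, query$prot_pos, query$ref_aa,
                                  query$alt_aa)
    if (stop_gain_auto_pathogenic(gene, mapping, config)) {
      evidence$label <- "Pathogenic"
      evidence$reason <- "stop_gain"
      evidence$stop_gain <- TRUE
      if (config$use_hotspot) {
        evidence$hotspot <- in_functional_hotspot(
          records, query$gene, query$prot_pos, config$range_aa,
          query$ref_aa, query$alt_aa)
        evidence$phenotype <- predict_phenotype(
          records, query$gene, query$prot_pos, config$range_aa,
          query$ref_aa, query$alt_aa)
      }
      return(structure(evidence, class = "ClassificationResult"))
    }
  }

  # (2) functional-hotspot screen
  if (config$use_hotspot) {
    evidence$hotspot <- in_functional_hotspot(
      records, query$gene, query$prot_pos, config$range_aa,
      query$ref_aa, query$alt_aa)
    evidence$phenotype <- predict_phenotype(
      records, query$gene, query$prot_pos, config$range_aa,
      query$ref_aa, query$alt_aa)
    if (!evidence$hotspot) {
      evidence$label <- "Benign(h)"
      evidence$reason <- "no_hotspot"
      return(structure(evidence, class = "ClassificationResult"))
    }
  }

  # conservation evidence; undefined WPC surfaces with partial evidence
  evidence$wpc <- tryCatch(
    wpc_score(combined_aln, query$prot_pos, query$ref_aa),
    snpcons_undefined_wpc = function(e) {
      stop(structure(
        class = c("snpcons_classification_error", "error", "condition"),
        list(message = conditionMessage(e), call = NULL,
             evidence = evidence)))
    })

  # (3) PSIC benign filter
  if (config$use_psic && query$alt_aa != "*") {
    if (is.null(profile)) profile <- psic_profile(combined_aln)
    evidence$psic <- psic_delta(profile, query$prot_pos,
                                query$ref_aa, query$alt_aa)
    if (evidence$psic < config$psic_cutoff) {
      evidence$label <- "Benign(a)"
      evidence$reason <- "psic_low"
      return(structure(evidence, class = "ClassificationResult"))
    }
  }

  # (4) WPC decision
  cutoff <- if (config$use_psic) config$wpc_cutoff_with_psic
            else config$wpc_cutoff_default
  if (evidence$wpc >= cutoff) {
    evidence$label <- "Pathogenic"
    evidence$reason <- "wpc_high"
  } else {
    evidence$label <- "Benign(a)"
    evidence$reason <- "wpc_low"
  }
  structure(evidence, class = "ClassificationResult")
}

#' @export
print.ClassificationResult <- function(x, ...) {
  cat("<ClassificationResult> ", x$query$gene, " p.", x$query$ref_aa,
      x$query$prot_pos, x$query$alt_aa, " -> ", x$label,
      " [", x$reason, "]",
      if (!is.na(x$wpc)) sprintf(" WPC=%.1f", x$wpc),
      if (!is.na(x$psic)) sprintf(" PSIC=%.2f", x$psic),
      "\n", sep = "")
  invisible(x)
}

#' Tabulate classification results
#' @param results List of `ClassificationResult` objects.
#' @return data.frame with one row per result (the results-TSV schema).
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(gene = r$query$gene, prot_pos = r$query$prot_pos,
               ref_aa = r$query$ref_aa, alt_aa = r$query$alt_aa,
               label = r$label, reason = r$reason,
               wpc = r$wpc, psic = r$psic, hotspot = r$hotspot,
               phenotype_status = r$phenotype$status,
               phenotype = r$phenotype$phenotype,
               support = r$phenotype$support,
               total_in_window = r$phenotype$total_in_window,
               stringsAsFactors = FALSE)
  }))
}

#' Classify a batch of queries
#'
#' Applies [classify_variant()] to each row of a batch table. Row-level
#' failures are recorded and do not abort the batch; results keep input
#' order.
#'
#' @param batch data.frame with columns `gene`, `query`, or a path to such
#'   a TSV.
#' @param bundle Resource bundle from [load_gene_bundle()] (per-gene
#'   `GeneRecord`s, combined alignments, known-variant table).
#' @param config A `PipelineConfig`.
#' @return List with `results` (list of `ClassificationResult`), `errors`
#'   (data.frame row/gene/query/message), `table` (results data.frame).
#' @export
classify_batch <- function(batch, bundle, config = pipeline_config()) {
  if (is.character(batch)) batch <- read_batch(batch)
  results <- list()
  errors <- list()
  profiles <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(batch))) {
    sym <- batch$gene[i]
    res <- tryCatch({
      gene <- bundle$genes[[sym]]
      if (is.null(gene)) stop("unknown gene '", sym, "'", call. = FALSE)
      aln <- bundle$alignments[[sym]]
      if (is.null(aln)) stop("no combined alignment for '", sym, "'",
                             call. = FALSE)
      prof <- if (config$use_psic) {
        if (is.null(profiles[[sym]])) profiles[[sym]] <- psic_profile(aln)
        profiles[[sym]]
      } else NULL
      classify_variant(batch$query[i], gene, aln, bundle$records, config,
                       profile = prof)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        data.frame(row = i, gene = sym, query = batch$query[i],
                   message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  list(results = results,
       errors = if (length(errors)) do.call(rbind, errors) else
         data.frame(row = integer(0), gene = character(0),
                    query = character(0), message = character(0)),
       table = if (length(results)) results_table(results) else NULL)
}
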