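disease_associated <- function(records) {
  records$classification %in% c("pathogenic", "unspecified_functional")
}

window_records <- function(records, gene, prot_pos, range_aa,
                           ref_aa = NULL, alt_aa = NULL) {
  recs <- records[records$gene == gene, , drop = FALSE]
  # exclude the query variant itself when identifiable
  if (!is.null(ref_aa) && !is.null(alt_aa)) {
    self <- recs$prot_pos == prot_pos & recs$ref_aa == ref_aa &
      recs$alt_aa == alt_aa
  } else {
    self <- recs$prot_pos == prot_pos
  }
  recs <- recs[!self, , drop = FALSE]
  recs[abs(recs$prot_pos - prot_pos) <= range_aa, , drop = FALSE]
}

#' Functional-hotspot membership
#'
#' A position lies in a functional hotspot when at least one known
#' disease-associated variant (classification `pathogenic` or
#' `unspecified_functional`) on the same gene lies within `range_aa` amino
#' acids (inclusive at both boundaries). Hotspots are deliberately broad:
#' any number of such records, including one, qualifies. The query variant
#' itself is excluded: by exact substitution match when `ref_aa`/`alt_aa`
#' are supplied, by position otherwise.
#'
#' @param records Known-variant data.frame ([read_known_variants()]).
#' @param gene Gene symbol.
#' @param prot_pos 1-based protein position.
#' @param range_aa Window half-width in amino acids (default 100).
#' @param ref_aa,alt_aa Optional query residues for self-exclusion.
#' @return Logical flag.
#' @export
in_functional_hotspot <- function(records, gene, prot_pos, range_aa = 100L,
                                  ref_aa = NULL, alt_aa = NULL) {
  recs <- window_records(records, gene, prot_pos, range_aa, ref_aa, alt_aa)
  any(disease_associated(recs))
}

#' Phenotype prediction by windowed frequency ranking
#'
#' Tallies the named phenotypes of known disease-associated variants within
#' `range_aa` amino acids of the query position and predicts the most
#' frequent one. Records classified `unspecified_functional` (and
#' pathogenic records without a named phenotype) count toward the window
#' total but never contribute a named phenotype; if the window holds only
#' such records the status is `functional_only` (high functional
#' significance, no specific condition). An empty window yields `no_data`.
#' Frequency ties are broken by the phenotype of the record nearest the
#' query position, residual ties lexicographically.
#'
#' @inheritParams in_functional_hotspot
#' @return List of class `PhenotypePrediction`: `status` (`predicted`,
#'   `functional_only`, `no_data`), `phenotype`, `support`,
#'   `total_in_window`, `nearest_distance`.
#' @export
predict_phenotype <- function(records, gene, prot_pos, range_aa = 100L,
                              ref_aa = NULL, alt_aa = NULL) {
  recs <- window_records(records, gene, prot_pos, range_aa, ref_aa, alt_aa)
  recs <- recs[disease_associated(recs), , drop = FALSE]
  total <- nrow(recs)
  if (total == 0L) {
    return(structure(list(status = "no_data", phenotype = "",
                          support = 0L, total_in_window = 0L,
                          nearest_distance = NA_integer_),
                     class = "PhenotypePrediction"))
  }
  nearest <- min(abs(recs$prot_pos - prot_pos))
  named <- recs[recs$classification == "pathogenic" & nzchar(recs$phenotype), ,
                drop = FALSE]
  if (nrow(named) == 0L) {
    return(structure(list(status = "functional_only", phenotype = "",
                          support = 0L, total_in_window = total,
                          nearest_distance = nearest),
                     class = "PhenotypePrediction"))
  }
  tab <- table(named$phenotype)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    cand <- named[named$phenotype %in% top, , drop = FALSE]
    cand <- cand[order(abs(cand$prot_pos - prot_pos), cand$phenotype), ,
                 drop = FALSE]
    winner <- cand$phenotype[1L]
  } else {
    winner <- top
  }
  structure(list(status = "predicted", phenotype = winner,
                 support = as.integer(tab[[winner]]),
                 total_in_window = total,
                 nearest_distance = nearest),
            class = "PhenotypePrediction")
}

#' @export
print.PhenotypePrediction <- function(x, ...) {
  cat("<PhenotypePrediction> ", x$status,
      if (x$status == "predicted") paste0(": ", x$phenotype, " (", x$support,
                                          "/", x$total_in_window, ")"),
      "\n", sep = "")
  invisible(x)
}
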