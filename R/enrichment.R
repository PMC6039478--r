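## Enrichment factors over ranked screening output with active/decoy
## labels: EF = (Hits_sampled / N_sampled) / (Hits_total / N_total).

#' Enrichment factor at a rank fraction
#'
#' The full labelled library defines `N_total`; ligands absent from the
#' ranking (screening non-hits) rank below every hit and are never counted
#' as retrieved actives -- an empty hit list therefore scores `EF = 0`.
#' `N_sampled = ceiling(fraction * N_total)`, so a 1% cut of any library
#' with at least one compound samples at least one.
#'
#' @param ranked character vector of ligand ids, best first.
#' @param labels named character vector (`"active"` / `"decoy"`) covering
#'   every ligand in the library, ranked or not.
#' @param fraction sampling fraction in (0, 1].
#' @return list (`EnrichmentResult`): `fraction`, `Hits_sampled`,
#'   `N_sampled`, `Hits_total`, `N_total`, `EF`. `EF` is `NA` when the
#'   library holds no actives (undefined).
#' @export
enrichment_factor <- function(ranked, labels, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (any(!ranked %in% names(labels)))
    stop("every ranked ligand must be labelled")
  n_total <- length(labels)
  hits_total <- sum(labels == "active")
  n_sampled <- as.integer(ceiling(fraction * n_total))
  top <- ranked[seq_len(min(n_sampled, length(ranked)))]
  hits_sampled <- if (length(top)) sum(labels[top] == "active") else 0L
  ef <- if (hits_total == 0) NA_real_
  else (hits_sampled / n_sampled) / (hits_total / n_total)
  list(fraction = fraction, Hits_sampled = hits_sampled,
       N_sampled = n_sampled, Hits_total = hits_total, N_total = n_total,
       EF = ef)
}

#' Enrichment report at the standard fractions
#'
#' @param hits hit table from [screen_library()] (or a character vector of
#'   ranked ids).
#' @param labels named label vector, as in [enrichment_factor()].
#' @param fractions rank fractions to evaluate (default 1%, 5%, 10%).
#' @return data.frame with one row per fraction; the `EF_label` column
#'   renders undefined values as `"-"` (no actives, or nothing screened
#'   because the model was empty).
#' @export
enrichment_report <- function(hits, labels, fractions = c(0.01, 0.05, 0.10)) {
  ranked <- if (is.character(hits)) hits else hits$ligand
  rows <- lapply(fractions, function(f) {
    r <- enrichment_factor(ranked, labels, f)
    data.frame(fraction = r$fraction, Hits_sampled = r$Hits_sampled,
               N_sampled = r$N_sampled, Hits_total = r$Hits_total,
               N_total = r$N_total, EF = r$EF,
               EF_label = if (is.na(r$EF)) "-" else sprintf("%.1f", r$EF),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.character(hits) && identical(attr(hits, "status"),
      "no feature was generated, and thus no compound was screened")) {
    out$EF <- NA_real_
    out$EF_label <- "-"
  }
  out
}
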