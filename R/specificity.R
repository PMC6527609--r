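#' eGenes significant in every condition
#'
#' Selects genes whose gene-level q-value is strictly below \code{q} in
#' all conditions — the discovery set for tissue-selectivity
#' classification, since condition-shared eQTLs are unlikely to be
#' treatment artifacts.
#'
#' @param calls data.frame with gene, condition, q_value.
#' @param q Discovery FDR level (default 0.05, strict <).
#' @return Character vector of shared eGenes.
#' @export
shared_egenes <- function(calls, q = 0.05) {
  if (!nrow(calls)) return(character(0))
  conds <- unique(calls$condition)
  if (length(conds) < 2L) stop("need >= 2 conditions", call. = FALSE)
  ok <- tapply(calls$q_value < q & !is.na(calls$q_value), calls$gene,
               function(x) sum(x) == length(conds))
  names(ok)[ok]
}

#' Two-step FDR tissue-selective eGene classification
#'
#' A discovery eGene is tissue-selective if no reference tissue shows a
#' significant association at the relaxed replication threshold: all
#' panel q-values must be >= \code{q_replication} (strict < counts as
#' replicated). Genes absent from the panel, or with only missing
#' entries, count as not significant anywhere and are therefore
#' selective.
#'
#' @param discovery Character vector of discovery eGenes.
#' @param panel Matrix or data.frame of gene x reference-tissue q-values
#'   (rownames = genes; NA allowed).
#' @param q_replication Replication FDR level (default 0.1).
#' @return Character vector (subset of \code{discovery}).
#' @export
tissue_selective_egenes <- function(discovery, panel, q_replication = 0.1) {
  panel <- as.matrix(panel)
  vapply(discovery, function(g) {
    if (!g %in% rownames(panel)) return(TRUE)
    qv <- panel[g, ]
    !any(qv < q_replication, na.rm = TRUE)
  }, logical(1)) -> selective
  discovery[selective]
}

#' Overlap between two gene lists
#'
#' @param set_a,set_b Character vectors.
#' @return List: n_a, n_b, intersection (size), fraction_a_in_b.
#' @export
overlap_summary <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  inter <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), intersection = inter,
       fraction_a_in_b = if (length(a)) inter / length(a) else NA_real_)
}
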