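## Hypergeometric term enrichment of a study gene set against a population
## with user-supplied gene-to-term annotation, Benjamini-Hochberg FDR per
## namespace, and the rich factor k/K used for dot plots.

#' Hypergeometric term enrichment
#'
#' For every term with at least `min_k` annotated population genes, the
#' upper-tail probability P[X >= k] of drawing k study genes with the term
#' is computed from the hypergeometric(N, K, n) distribution. FDR is
#' Benjamini-Hochberg, applied separately within each annotation namespace
#' when a `namespace` column is present.
#'
#' @param study character vector of study genes (must be a subset of the
#'   population).
#' @param population character vector of background genes.
#' @param annotation data.frame with `gene_id`, `term_id`, `term_name`
#'   and optionally `namespace`.
#' @param fdr_max significance threshold (0.05).
#' @param min_k minimum population genes per testable term (terms below
#'   are skipped).
#' @return data.frame: term_id, term_name, namespace, k, K, n, N, p, fdr,
#'   rich_factor, significant; sorted by fdr then p.
#' @export
enrich_terms <- function(study, population, annotation, fdr_max = 0.05,
                         min_k = 2L) {
  study <- unique(study)
  population <- unique(population)
  bad <- setdiff(study, population)
  if (length(bad)) {
    stop("study genes absent from population: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  ann <- annotation[annotation$gene_id %in% population, , drop = FALSE]
  ann <- unique(ann[, intersect(c("gene_id", "term_id", "term_name",
                                  "namespace"), names(ann))])
  if (!nrow(ann)) stop("annotation covers no population gene")
  if (!"namespace" %in% names(ann)) ann$namespace <- "all"
  N <- length(population)
  n <- length(study)
  terms <- unique(ann[, c("term_id", "term_name", "namespace")])
  K <- table(ann$term_id)
  in_study <- ann[ann$gene_id %in% study, , drop = FALSE]
  k <- table(in_study$term_id)
  terms$K <- as.integer(K[terms$term_id])
  terms$k <- as.integer(k[terms$term_id])
  terms$k[is.na(terms$k)] <- 0L
  skipped <- terms$K < min_k
  if (any(skipped)) {
    message(sum(skipped), " terms with K < ", min_k, " skipped")
  }
  terms <- terms[!skipped, , drop = FALSE]
  terms$n <- n
  terms$N <- N
  terms$p <- stats::phyper(terms$k - 1L, terms$K, N - terms$K, n,
                           lower.tail = FALSE)
  terms$fdr <- NA_real_
  for (ns in unique(terms$namespace)) {
    i <- terms$namespace == ns
    terms$fdr[i] <- stats::p.adjust(terms$p[i], method = "BH")
  }
  terms$rich_factor <- ifelse(terms$K > 0, terms$k / terms$K, NA)
  terms$significant <- terms$fdr <= fdr_max
  terms <- terms[order(terms$fdr, terms$p, terms$term_id), , drop = FALSE]
  rownames(terms) <- NULL
  terms[, c("term_id", "term_name", "namespace", "k", "K", "n", "N", "p",
            "fdr", "rich_factor", "significant")]
}

#' Plot-ready table of significant terms
#'
#' @param results output of [enrich_terms()].
#' @return data.frame (term_id, term_name, rich_factor, k, fdr) for the
#'   significant terms, ordered by fdr.
#' @export
rich_factor_table <- function(results) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  out <- sig[order(sig$fdr), c("term_id", "term_name", "rich_factor", "k",
                               "fdr")]
  rownames(out) <- NULL
  out
}
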