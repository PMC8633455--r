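## Integration of DE-miRNAs with their candidate target genes (CTGs):
## pair construction (DE-miRNA x predicted target that is itself a DEG in
## the same comparison), Pearson correlation of expression profiles over
## the replicate libraries of the two compared stages (n = 6 by default),
## and the three-way classification: negative (-1 < r < -0.8, p <= 0.05),
## positive (r > 0.8, p <= 0.05, mirrored convention) or none.

#' Build DE-miRNA / CTG pairs for one comparison
#'
#' @param de_mirnas data.frame from [call_de_mirnas()] (one comparison).
#' @param hits target hits from [scan_transcriptome()].
#' @param degs data.frame from [call_degs()] (same comparison).
#' @return data.frame (mirna, ctg, comparison), duplicates removed.
#' @export
build_pairs <- function(de_mirnas, hits, degs) {
  cmp <- unique(c(unique(de_mirnas$comparison), unique(degs$comparison)))
  if (length(cmp) != 1) {
    stop("inputs come from different comparisons: ",
         paste(cmp, collapse = ", "))
  }
  de_m <- de_mirnas$feature[de_mirnas$called]
  de_g <- degs$feature[degs$called]
  sel <- hits$mirna %in% de_m & hits$transcript %in% de_g
  pairs <- unique(data.frame(mirna = hits$mirna[sel],
                             ctg = hits$transcript[sel],
                             row.names = NULL))
  if (nrow(pairs)) pairs$comparison <- cmp
  else pairs$comparison <- character(0)
  rownames(pairs) <- NULL
  pairs
}

#' Pearson correlation of one miRNA/gene expression pair
#'
#' @param mirna_profile,ctg_profile numeric expression vectors over the
#'   same libraries (>= 3 values).
#' @return list with `r` and two-sided `p` from the t transform with
#'   n - 2 degrees of freedom; `r` is NA (with a warning) when either
#'   profile has zero variance.
#' @export
correlate_pair <- function(mirna_profile, ctg_profile) {
  n <- length(mirna_profile)
  stopifnot(n == length(ctg_profile), n >= 3)
  if (stats::sd(mirna_profile) == 0 || stats::sd(ctg_profile) == 0) {
    warning("zero variance profile; correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(mirna_profile, ctg_profile)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Correlate and classify DE-miRNA/CTG pairs
#'
#' @param pairs data.frame from [build_pairs()].
#' @param mirna_expr miRNA TPM matrix (features x libraries).
#' @param gene_expr gene FPKM matrix.
#' @param libraries library ids over which to correlate (the replicate
#'   libraries of the two compared stages).
#' @param log_transform correlate log2(x + 1) profiles (default TRUE).
#' @param r_neg,p_max class boundaries: negative iff
#'   -1 < r < `r_neg` and p <= `p_max`; positive iff r > -`r_neg` and
#'   p <= `p_max`.
#' @return list with `records` (pair table with r, p, cls) and `summary`.
#' @export
classify_pairs <- function(pairs, mirna_expr, gene_expr, libraries,
                           log_transform = TRUE, r_neg = -0.8,
                           p_max = 0.05) {
  tf <- if (log_transform) function(x) log2(x + 1) else identity
  rec <- pairs
  rec$r <- NA_real_
  rec$p <- NA_real_
  rec$cls <- "none"
  for (i in seq_len(nrow(rec))) {
    x <- tf(as.numeric(mirna_expr[rec$mirna[i], libraries]))
    y <- tf(as.numeric(gene_expr[rec$ctg[i], libraries]))
    cp <- withCallingHandlers(
      correlate_pair(x, y),
      warning = function(w) invokeRestart("muffleWarning"))
    rec$r[i] <- cp$r
    rec$p[i] <- cp$p
  }
  neg <- !is.na(rec$r) & rec$r > -1 & rec$r < r_neg & rec$p <= p_max
  pos <- !is.na(rec$r) & rec$r > -r_neg & rec$p <= p_max
  rec$cls[neg] <- "negative"
  rec$cls[pos] <- "positive"
  summary <- data.frame(
    comparison = if (nrow(rec)) rec$comparison[1] else NA,
    n_pairs = nrow(rec),
    n_negative = sum(rec$cls == "negative"),
    n_positive = sum(rec$cls == "positive"),
    n_none = sum(rec$cls == "none"),
    n_unique_mirnas = length(unique(rec$mirna)),
    n_unique_ctgs = length(unique(rec$ctg)),
    r_neg_min = if (any(neg)) min(rec$r[neg]) else NA_real_,
    r_neg_max = if (any(neg)) max(rec$r[neg]) else NA_real_,
    row.names = NULL)
  list(records = rec, summary = summary)
}

#' Unique DE-miRNAs and CTGs among negative pairs, plus an edge list
#'
#' @param records pair records from [classify_pairs()].
#' @return list with `n_mirnas`, `n_ctgs` (set cardinalities over the
#'   negative class) and `edges` (source, target, sign) for network
#'   rendering.
#' @export
dedupe_network <- function(records) {
  neg <- records[records$cls == "negative", , drop = FALSE]
  edges <- data.frame(source = neg$mirna, target = neg$ctg,
                      sign = rep("negative", nrow(neg)), row.names = NULL)
  list(n_mirnas = length(unique(neg$mirna)),
       n_ctgs = length(unique(neg$ctg)),
       edges = edges)
}
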