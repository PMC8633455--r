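## Normalisation and differential expression.
##
## miRNA abundances are normalised as TPM = count / total clean reads x 1e6
## (totals are total clean reads of the library, not total miRNA reads);
## gene abundances as FPKM. Differential expression uses an exact
## conditional negative-binomial test: given the total count of a feature
## over both groups, the group-A sum follows a conditional distribution
## that is binomial at dispersion zero and an NB convolution otherwise;
## the two-sided p doubles the smaller tail. miRNAs are called at
## |log2FC| >= 1 and p <= 0.05, genes at |log2FC| >= 1 and BH FDR <= 0.05.

#' TPM-normalise a count matrix
#'
#' @param counts features x libraries matrix of raw counts.
#' @param totals per-library totals to normalise against (total clean
#'   reads; defaults to column sums).
#' @return numeric matrix of TPM values.
#' @export
tpm_normalize <- function(counts, totals = colSums(counts)) {
  if (any(totals <= 0)) {
    stop("zero-total library: ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' FPKM-normalise a count matrix
#'
#' @param counts features x libraries matrix of fragment counts.
#' @param lengths per-feature lengths in nt (named or positionally
#'   matched).
#' @param totals mapped-fragment totals per library (defaults to column
#'   sums).
#' @export
fpkm_normalize <- function(counts, lengths, totals = colSums(counts)) {
  if (length(lengths) != nrow(counts) || any(is.na(lengths)) ||
      any(lengths <= 0)) {
    stop("missing or invalid feature lengths")
  }
  if (any(totals <= 0)) {
    stop("zero-total library: ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(sweep(counts, 1, lengths / 1e3, "/"), 2, totals / 1e6, "/")
}

#' Exact conditional negative-binomial test for one feature
#'
#' Conditions on the total count across both groups. At dispersion zero
#' the conditional law of the group-A sum is binomial; otherwise it is the
#' convolution ratio of the two group NB sums (sum of n iid NB(mu, 1/phi)
#' is NB with size n/phi). Unequal library sizes are first adjusted by
#' scaling counts to the geometric-mean library size. The two-sided p
#' doubles the smaller tail, capped at 1.
#'
#' @param counts_a,counts_b integer replicate counts per group.
#' @param dispersion NB dispersion phi >= 0.
#' @param lib_sizes optional concatenated library sizes (a then b) used
#'   for the equal-size adjustment.
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion = 0,
                          lib_sizes = NULL) {
  stopifnot(length(counts_a) >= 1, length(counts_b) >= 1, dispersion >= 0)
  if (!is.null(lib_sizes)) {
    stopifnot(length(lib_sizes) == length(counts_a) + length(counts_b))
    ref <- exp(mean(log(lib_sizes)))
    adj <- round(c(counts_a, counts_b) * ref / lib_sizes)
    counts_a <- adj[seq_along(counts_a)]
    counts_b <- adj[-seq_along(counts_a)]
  }
  na <- length(counts_a)
  nb <- length(counts_b)
  sa <- sum(counts_a)
  total <- sa + sum(counts_b)
  if (total == 0) return(1.0)
  if (dispersion < 1e-12) {
    pa <- na / (na + nb)
    lower <- stats::pbinom(sa, total, pa)
    upper <- stats::pbinom(sa - 1, total, pa, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  mu_a <- total * na / (na + nb)
  mu_b <- total - mu_a
  x <- 0:total
  lw <- stats::dnbinom(x, size = na / dispersion, mu = mu_a, log = TRUE) +
    stats::dnbinom(total - x, size = nb / dispersion, mu = mu_b, log = TRUE)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  lower <- sum(w[x <= sa])
  upper <- sum(w[x >= sa])
  min(1, 2 * min(lower, upper))
}

#' Method-of-moments common dispersion across features
#'
#' Counts are scaled to the geometric-mean library size, within-group
#' means and variances pooled, and the ratio of summed excess variance to
#' summed squared mean taken as the common dispersion (floored at 1e-6).
#'
#' @param counts features x libraries matrix.
#' @param groups factor of group labels per library.
#' @param lib_sizes library sizes (defaults to column sums).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       lib_sizes = colSums(counts)) {
  ref <- exp(mean(log(pmax(lib_sizes, 1))))
  sc <- sweep(counts, 2, ref / lib_sizes, "*")
  num <- 0
  den <- 0
  for (g in unique(groups)) {
    m <- sc[, groups == g, drop = FALSE]
    if (ncol(m) < 2) next
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    num <- num + sum(v - mu)
    den <- den + sum(mu^2)
  }
  if (den <= 0) return(1e-6)
  max(1e-6, min(5, num / den))
}

de_table <- function(counts, norm, groups, comparison, totals, dispersion,
                     lfc_pseudo) {
  earlier <- comparison[1]
  later <- comparison[2]
  if (!all(comparison %in% groups)) {
    stop("unknown stage label in comparison: ",
         paste(setdiff(comparison, groups), collapse = ", "))
  }
  ia <- which(groups == earlier)
  ib <- which(groups == later)
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(
      counts[, c(ia, ib), drop = FALSE],
      factor(groups[c(ia, ib)]), totals[c(ia, ib)])
  }
  lfc <- log2((rowMeans(norm[, ib, drop = FALSE]) + lfc_pseudo) /
                (rowMeans(norm[, ia, drop = FALSE]) + lfc_pseudo))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(counts[i, ia], counts[i, ib], dispersion,
                  lib_sizes = totals[c(ia, ib)])
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(feature = rownames(counts),
             comparison = paste0(later, "/", earlier),
             log2fc = lfc, p = p, fdr = fdr,
             direction = ifelse(lfc >= 0, "up", "down"),
             dispersion = dispersion, row.names = NULL)
}

#' Call differentially expressed miRNAs for one stage comparison
#'
#' Fold changes are log2 of mean TPM (with a pseudocount) of the later
#' stage over the earlier; p-values come from [nb_exact_test()] on raw
#' counts with a common method-of-moments dispersion. A miRNA is called
#' when |log2FC| >= `lfc_min` and p <= `p_max`.
#'
#' @param counts features x libraries raw count matrix.
#' @param totals per-library total clean reads (TPM denominators and
#'   library sizes).
#' @param groups stage label per library.
#' @param comparison character pair c(earlier, later); the reported fold
#'   change is later/earlier.
#' @param dispersion NB dispersion; estimated when `NULL`.
#' @param lfc_min,p_max calling thresholds.
#' @param lfc_pseudo pseudocount (TPM units) applied to both means.
#' @return data.frame: feature, comparison, log2fc, p, fdr, called,
#'   direction.
#' @export
call_de_mirnas <- function(counts, totals, groups, comparison,
                           dispersion = NULL, lfc_min = 1, p_max = 0.05,
                           lfc_pseudo = 0.5) {
  tpm <- tpm_normalize(counts, totals)
  res <- de_table(counts, tpm, groups, comparison, totals, dispersion,
                  lfc_pseudo)
  res$called <- abs(res$log2fc) >= lfc_min & res$p <= p_max
  res
}

#' Call differentially expressed genes for one stage comparison
#'
#' Same test as [call_de_mirnas()] but fold changes use FPKM and calling
#' uses the Benjamini-Hochberg FDR (<= `fdr_max`) instead of the raw p.
#'
#' @inheritParams call_de_mirnas
#' @param lengths per-gene lengths (nt) for FPKM.
#' @param fdr_max FDR threshold.
#' @export
call_degs <- function(counts, lengths, groups, comparison, totals = NULL,
                      dispersion = NULL, lfc_min = 1, fdr_max = 0.05,
                      lfc_pseudo = 0.5) {
  if (is.null(totals)) totals <- colSums(counts)
  fpkm <- fpkm_normalize(counts, lengths, totals)
  res <- de_table(counts, fpkm, groups, comparison, totals, dispersion,
                  lfc_pseudo)
  res$called <- abs(res$log2fc) >= lfc_min & res$fdr <= fdr_max
  res
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - Ct(reference) is averaged over
#' replicates; ddCt subtracts the calibrator sample's mean dCt, giving a
#' relative expression of exactly 1 for the calibrator. The standard error
#' is taken over the per-replicate 2^-ddCt values.
#'
#' @param ct data.frame with columns `sample`, `assay`, `replicate`, `ct`.
#' @param target_assay assay to quantify.
#' @param reference_assay endogenous reference assay (e.g. 5.8S rRNA for
#'   miRNAs, beta-actin for genes).
#' @param calibrator_sample sample whose expression defines 1.
#' @return data.frame: sample, rel_expr, se, n_replicates.
#' @export
delta_delta_ct <- function(ct, target_assay, reference_assay,
                           calibrator_sample) {
  stopifnot(all(c("sample", "assay", "replicate", "ct") %in% names(ct)))
  tgt <- ct[ct$assay == target_assay, , drop = FALSE]
  ref <- ct[ct$assay == reference_assay, , drop = FALSE]
  key <- function(d) paste(d$sample, d$replicate, sep = "\r")
  m <- match(key(tgt), key(ref))
  if (anyNA(m)) {
    stop("missing reference Ct for: ",
         paste(unique(tgt$sample[is.na(m)]), collapse = ", "))
  }
  dct <- tgt$ct - ref$ct[m]
  samples <- unique(tgt$sample)
  if (!calibrator_sample %in% samples) stop("calibrator sample not found")
  cal_mean <- mean(dct[tgt$sample == calibrator_sample])
  out <- lapply(samples, function(s) {
    d <- dct[tgt$sample == s]
    rel_reps <- 2^-(d - cal_mean)
    data.frame(sample = s,
               rel_expr = 2^-(mean(d) - cal_mean),
               se = if (length(d) > 1) stats::sd(rel_reps) / sqrt(length(d))
                    else NA_real_,
               n_replicates = length(d), row.names = NULL)
  })
  do.call(rbind, out)
}
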