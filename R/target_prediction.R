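## miRNA target prediction: ungapped antiparallel alignment of the miRNA
## against every transcript window of equal length, scored per position as
## 0 (Watson-Crick), 0.5 (G:U wobble) or 1 (mismatch), with positions
## numbered from the miRNA 5' end. Six acceptance rules:
##   1. total weighted mismatches <= 4
##   2. no more than two adjacent mismatch positions (a non-Watson-Crick
##      position counts toward adjacency; strict default)
##   3. no adjacent full mismatches within positions 2-12
##   4. no mismatch at positions 10-11 (strict default: G:U also rejects)
##   5. at most 2.5 weighted mismatches within positions 1-12
##   6. duplex MFE >= 74% of the MFE of the miRNA bound to its perfect
##      complement (ratio of magnitudes).

#' Rule set for duplex scoring
#'
#' @param max_total rule 1 cap on total weighted mismatches.
#' @param max_adjacent rule 2: longest allowed run of non-Watson-Crick
#'   positions.
#' @param adjacency_counts_gu whether a G:U counts as a mismatch event for
#'   rule 2 adjacency (strict default TRUE).
#' @param seed_adjacency_full rule 3: when TRUE (default) only runs of two
#'   full mismatches in positions 2-12 reject; when FALSE any two adjacent
#'   non-Watson-Crick positions reject.
#' @param cleavage_strict rule 4: when TRUE (default) a G:U at positions
#'   10-11 rejects; when FALSE only full mismatches reject.
#' @param max_seed_total rule 5 cap over positions 1-12.
#' @param mfe_ratio_min rule 6 threshold on |MFE site| / |MFE perfect|.
#' @export
target_rules <- function(max_total = 4, max_adjacent = 2,
                         adjacency_counts_gu = TRUE,
                         seed_adjacency_full = TRUE,
                         cleavage_strict = TRUE, max_seed_total = 2.5,
                         mfe_ratio_min = 0.74) {
  list(max_total = max_total, max_adjacent = max_adjacent,
       adjacency_counts_gu = adjacency_counts_gu,
       seed_adjacency_full = seed_adjacency_full,
       cleavage_strict = cleavage_strict, max_seed_total = max_seed_total,
       mfe_ratio_min = mfe_ratio_min)
}

## per-position weighted mismatch values for an ungapped antiparallel
## duplex; position p of the miRNA (from its 5' end) faces site position
## L - p + 1
mismatch_vector <- function(mirna, site) {
  mv <- strsplit(as_rna(mirna), "")[[1]]
  sv <- rev(strsplit(as_rna(site), "")[[1]])
  wc <- (mv == "A" & sv == "U") | (mv == "U" & sv == "A") |
    (mv == "G" & sv == "C") | (mv == "C" & sv == "G")
  gu <- (mv == "G" & sv == "U") | (mv == "U" & sv == "G")
  ifelse(wc, 0, ifelse(gu, 0.5, 1))
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Score a miRNA/site duplex against the positional rules
#'
#' @param mirna miRNA sequence (RNA, 18-25 nt, 5'->3').
#' @param site candidate site of equal length (DNA or RNA, 5'->3' on the
#'   transcript).
#' @param rules rule set from [target_rules()].
#' @return object of class `duplex_hit`: mismatch vector, total, per-rule
#'   flags `r1`..`r5`, `rules_pass`, and empty energy slots filled by
#'   [mfe_ratio_filter()].
#' @export
score_duplex <- function(mirna, site, rules = target_rules()) {
  L <- nchar(mirna)
  if (L < 18 || L > 25) stop("miRNA must be 18-25 nt")
  if (nchar(site) != L) stop("site and miRNA lengths differ")
  v <- mismatch_vector(mirna, site)
  total <- sum(v)
  seed_hi <- min(12L, L)
  r1 <- total <= rules$max_total
  adj_event <- if (rules$adjacency_counts_gu) v >= 0.5 else v == 1
  r2 <- longest_run(adj_event) <= rules$max_adjacent
  seed_positions <- 2:seed_hi
  seed_event <- if (rules$seed_adjacency_full) {
    v[seed_positions] == 1
  } else {
    v[seed_positions] >= 0.5
  }
  r3 <- longest_run(seed_event) <= 1
  r4 <- if (rules$cleavage_strict) all(v[10:11] == 0) else all(v[10:11] < 1)
  r5 <- sum(v[1:seed_hi]) <= rules$max_seed_total
  structure(list(mirna = as_rna(mirna), site = toupper(site),
                 mismatch_vector = v, total_weighted = total,
                 r1 = r1, r2 = r2, r3 = r3, r4 = r4, r5 = r5,
                 rules_pass = r1 && r2 && r3 && r4 && r5,
                 mfe_site = NA_real_, mfe_perfect = NA_real_,
                 mfe_ratio = NA_real_),
            class = "duplex_hit")
}

#' Apply the duplex-energy ratio rule (rule 6)
#'
#' Computes (or reuses) the duplex MFE of the miRNA against the site and
#' against its own perfect complement and passes the hit when
#' |MFE site| / |MFE perfect| is at least `threshold`.
#'
#' @param hit a `duplex_hit` from [score_duplex()].
#' @param threshold minimum ratio (0.74).
#' @param par folding parameters.
#' @return logical; the evaluated hit is attached as attribute `hit`.
#' @export
mfe_ratio_filter <- function(hit, threshold = 0.74,
                             par = energy_parameters()) {
  stopifnot(inherits(hit, "duplex_hit"))
  if (is.na(hit$mfe_site)) {
    hit$mfe_site <- duplex_mfe(hit$mirna, hit$site, par)$mfe
  }
  if (is.na(hit$mfe_perfect)) {
    hit$mfe_perfect <- duplex_mfe(hit$mirna, revcomp(hit$mirna, "RNA"),
                                  par)$mfe
  }
  if (hit$mfe_perfect == 0) {
    warning("degenerate miRNA with no pairable perfect complement")
    res <- FALSE
    hit$mfe_ratio <- NA_real_
  } else {
    hit$mfe_ratio <- abs(hit$mfe_site) / abs(hit$mfe_perfect)
    res <- hit$mfe_ratio >= threshold - 1e-9
  }
  attr(res, "hit") <- hit
  res
}

## vectorised rule screen of one miRNA against one transcript; returns
## 5'-window start positions passing rules 1-5 plus their value columns
screen_windows <- function(mirna_rna, tx_codes, rules) {
  L <- nchar(mirna_rna)
  n <- length(tx_codes)
  if (n < L) return(NULL)
  nt <- n - L + 1L
  ## site position q faces miRNA position p = L - q + 1; express the
  ## expected complement in DNA codes (A=1, C=2, G=3, T=4)
  mv <- strsplit(mirna_rna, "")[[1]]
  comp_code <- c(A = 4L, C = 3L, G = 2L, U = 1L)[mv]   # WC partner of m[p]
  wob_code <- c(A = 0L, C = 0L, G = 4L, U = 3L)[mv]    # G:U partner
  V <- matrix(1, nrow = L, ncol = nt)
  for (q in seq_len(L)) {
    p <- L - q + 1L
    s <- tx_codes[q:(q + nt - 1L)]
    val <- rep(1, nt)
    val[s == comp_code[p]] <- 0
    if (wob_code[p] > 0L) val[s == wob_code[p]] <- 0.5
    V[p, ] <- val
  }
  total <- colSums(V)
  ok <- total <= rules$max_total
  seed_hi <- min(12L, L)
  ok <- ok & colSums(V[1:seed_hi, , drop = FALSE]) <= rules$max_seed_total
  if (rules$cleavage_strict) {
    ok <- ok & V[10, ] == 0 & V[11, ] == 0
  } else {
    ok <- ok & V[10, ] < 1 & V[11, ] < 1
  }
  ## rule 2: no run of > max_adjacent non-WC positions
  E <- if (rules$adjacency_counts_gu) V >= 0.5 else V == 1
  k <- rules$max_adjacent
  run <- matrix(TRUE, nrow = L - k, ncol = nt)
  for (d in 0:k) run <- run & E[(1 + d):(L - k + d), , drop = FALSE]
  ok <- ok & colSums(run) == 0
  ## rule 3: adjacent full mismatches in 2..12
  F1 <- V == 1
  pr <- 2:(seed_hi - 1L)
  ev <- if (rules$seed_adjacency_full) F1 else E
  adj <- ev[pr, , drop = FALSE] & ev[pr + 1L, , drop = FALSE]
  ok <- ok & colSums(adj) == 0
  idx <- which(ok)
  if (!length(idx)) return(NULL)
  list(starts = idx, totals = total[idx])
}

#' Scan transcripts for candidate target sites of a set of miRNAs
#'
#' Every sense-strand window of miRNA length is screened against rules
#' 1-5; surviving windows are evaluated for the duplex-energy ratio
#' (rule 6). Hits are deduplicated per (miRNA, transcript), keeping the
#' lowest total weighted mismatch, then the highest energy ratio, then the
#' smallest coordinate.
#'
#' @param mirnas named character vector of miRNA sequences (RNA).
#' @param transcripts named character vector of transcript sequences
#'   (DNA, spliced).
#' @param rules rule set from [target_rules()].
#' @param par folding parameters.
#' @return data.frame: mirna, transcript, site_start (1-based transcript
#'   coordinate of the position opposite miRNA position 1), window_start,
#'   site_seq, total_weighted, mfe_site, mfe_perfect, mfe_ratio.
#' @export
scan_transcriptome <- function(mirnas, transcripts, rules = target_rules(),
                               par = energy_parameters()) {
  stopifnot(length(transcripts) >= 1)
  tx_codes <- lapply(transcripts, function(s) {
    match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  })
  out <- list()
  for (mn in names(mirnas)) {
    mseq <- as_rna(mirnas[[mn]])
    L <- nchar(mseq)
    perfect <- duplex_mfe(mseq, revcomp(mseq, "RNA"), par)$mfe
    if (perfect == 0) next
    for (tn in names(transcripts)) {
      sc <- screen_windows(mseq, tx_codes[[tn]], rules)
      if (is.null(sc)) next
      best <- NULL
      for (k in seq_along(sc$starts)) {
        t0 <- sc$starts[k]
        site <- substr(transcripts[[tn]], t0, t0 + L - 1L)
        mfe_site <- duplex_mfe(mseq, site, par)$mfe
        ratio <- abs(mfe_site) / abs(perfect)
        if (ratio < rules$mfe_ratio_min - 1e-9) next
        cand <- list(t0 = t0, site = site, total = sc$totals[k],
                     mfe_site = mfe_site, ratio = ratio)
        if (is.null(best) ||
            cand$total < best$total ||
            (cand$total == best$total && cand$ratio > best$ratio)) {
          best <- cand
        }
      }
      if (!is.null(best)) {
        out[[length(out) + 1L]] <- data.frame(
          mirna = mn, transcript = tn,
          site_start = best$t0 + L - 1L, window_start = best$t0,
          site_seq = best$site, total_weighted = best$total,
          mfe_site = best$mfe_site, mfe_perfect = perfect,
          mfe_ratio = best$ratio, row.names = NULL)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      site_start = integer(0), window_start = integer(0),
                      site_seq = character(0), total_weighted = numeric(0),
                      mfe_site = numeric(0), mfe_perfect = numeric(0),
                      mfe_ratio = numeric(0)))
  }
  do.call(rbind, out)
}
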