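## Read cleaning. Small-RNA rule set: drop reads with more than one base at
## Phred <= 20 or any N; locate and trim the 3' adapter; drop 5'-adapter
## contamination, adapter dimers (no insert) and reads with no detectable
## 3' adapter; drop poly(A) inserts; require inserts of >= 18 nt. mRNA rule
## set: adapter-trim, then >= 50 nt, <= 10% N, <= 50% low-quality bases,
## applied pairwise. Categories are assigned in that order and every read
## lands in exactly one, so the report always sums to the raw total.

PHRED20_CLASS <- "[!-5]"  # Phred+33 characters with Q <= 20

count_chars <- function(x, pattern, fixed = FALSE) {
  nchar(x) - nchar(gsub(pattern, "", x, fixed = fixed))
}

## Leftmost occurrence of `adapter` in each sequence: exact match of the
## adapter's first `seed_len` bases, extended over the remaining adapter
## bases (as far as the read allows) with at most `max_mismatch` mismatches.
find_adapter <- function(seqs, adapter, seed_len = 8L, max_mismatch = 1L) {
  stopifnot(nchar(adapter) >= seed_len)
  seed <- substr(adapter, 1L, seed_len)
  la <- nchar(adapter)
  pos <- rep(NA_integer_, length(seqs))
  from <- rep(1L, length(seqs))
  active <- seq_along(seqs)
  while (length(active)) {
    sub <- substr(seqs[active], from[active], nchar(seqs[active]))
    p <- regexpr(seed, sub, fixed = TRUE)
    found <- which(p > 0L)
    if (!length(found)) break
    cand <- active[found]
    cand_pos <- from[cand] + as.integer(p[found]) - 1L
    ## fast path: the (possibly end-truncated) adapter matches exactly
    got <- substr(seqs[cand], cand_pos, cand_pos + la - 1L)
    good <- got == substr(adapter, 1L, nchar(got))
    ## slow path: count extension mismatches for the rest
    slow <- which(!good)
    if (length(slow) && la > seed_len) {
      mm <- integer(length(slow))
      n <- nchar(seqs[cand[slow]])
      for (k in (seed_len + 1L):la) {
        at <- cand_pos[slow] + k - 1L
        ok <- at <= n
        if (!any(ok)) break
        ch <- substr(seqs[cand[slow]], at, at)
        mm <- mm + as.integer(ok & ch != substr(adapter, k, k))
      }
      good[slow] <- mm <= max_mismatch
    }
    pos[cand[good]] <- cand_pos[good]
    ## retry failed candidates after this seed hit
    retry <- cand[!good]
    from[retry] <- cand_pos[!good] + 1L
    active <- retry[from[retry] + seed_len - 1L <= nchar(seqs[retry])]
  }
  pos
}

#' Classify the adapter content of small-RNA reads
#'
#' Adapters are located by an exact 8-nt seed of the adapter's 5' end,
#' extended over the rest of the adapter with at most one mismatch,
#' searching left to right. An insert that is >= 90% A after trimming is
#' classified `polyA`.
#'
#' @param seq character vector of read sequences.
#' @param adapter_3p,adapter_5p adapter sequences (DNA).
#' @param polya_frac A-fraction at or above which an insert counts as
#'   poly(A).
#' @return data.frame with columns `class` (one of `3p_only`, `5p_only`,
#'   `both_no_insert`, `none`, `polyA`) and `insert` (empty unless the
#'   class is `3p_only` or `polyA`).
#' @export
detect_adapter <- function(seq, adapter_3p, adapter_5p, polya_frac = 0.9) {
  stopifnot(nchar(adapter_3p) > 0, nchar(adapter_5p) > 0)
  seq <- toupper(seq)
  p5 <- find_adapter(seq, adapter_5p)
  p3 <- find_adapter(seq, adapter_3p)
  n <- length(seq)
  cls <- rep("none", n)
  insert <- rep("", n)
  has5 <- !is.na(p5)
  end5 <- ifelse(has5, p5 + nchar(adapter_5p) - 1L, NA_integer_)
  cls[has5] <- ifelse(!is.na(p3[has5]) & p3[has5] == end5[has5] + 1L,
                      "both_no_insert", "5p_only")
  only3 <- !has5 & !is.na(p3)
  insert[only3] <- substr(seq[only3], 1L, p3[only3] - 1L)
  cls[only3] <- "3p_only"
  polya <- only3 & nchar(insert) > 0 &
    count_chars(insert, "A", fixed = TRUE) / pmax(nchar(insert), 1L) >=
      polya_frac
  cls[polya] <- "polyA"
  data.frame(class = cls, insert = insert)
}

#' Clean small-RNA reads
#'
#' Applies, in order: malformed-record removal, low-quality removal (more
#' than one base at Phred <= 20, or any N), adapter classification and
#' trimming, poly(A)-insert removal, and the minimum insert length.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33), e.g. from
#'   [read_fastq()].
#' @param adapter_3p,adapter_5p adapter sequences.
#' @param min_len minimum insert length kept (18).
#' @param require_adapter drop reads with no detectable 3' adapter (the
#'   default, appropriate for raw libraries where the insert boundary is
#'   otherwise unknown). Set `FALSE` when re-filtering already-trimmed
#'   reads; the remaining filters are idempotent.
#' @param max_low_qual maximum number of bases at Phred <= 20.
#' @return list with `reads` (cleaned: trimmed seq/qual) and `report`
#'   (class `qc_report`).
#' @export
clean_srna_reads <- function(reads, adapter_3p, adapter_5p, min_len = 18L,
                             require_adapter = TRUE, max_low_qual = 1L) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  total <- nrow(reads)
  malformed <- nchar(reads$seq) != nchar(reads$qual)
  if (any(malformed)) {
    message(sum(malformed), " malformed records dropped")
  }
  r <- reads[!malformed, , drop = FALSE]

  nlow <- count_chars(r$qual, PHRED20_CLASS)
  nn <- count_chars(r$seq, "N", fixed = TRUE)
  lowq <- nlow > max_low_qual | nn > 0L

  cls <- rep("low_quality", nrow(r))
  insert <- rep("", nrow(r))
  ok <- !lowq
  if (any(ok)) {
    det <- detect_adapter(r$seq[ok], adapter_3p, adapter_5p)
    cls[ok] <- det$class
    insert[ok] <- det$insert
  }
  if (!require_adapter) {
    keepnone <- cls == "none"
    insert[keepnone] <- toupper(r$seq[keepnone])
    cls[keepnone] <- "3p_only"
  }
  short <- cls == "3p_only" & nchar(insert) < min_len
  cls[short] <- "short"

  category <- factor(cls, levels = c("low_quality", "5p_only",
                                     "both_no_insert", "none", "polyA",
                                     "short", "3p_only"))
  tab <- as.list(table(category))
  keep <- cls == "3p_only"
  out <- data.frame(id = r$id[keep],
                    seq = insert[keep],
                    qual = substr(r$qual[keep], 1L, nchar(insert[keep])),
                    row.names = NULL)
  report <- structure(list(
    total_raw = total,
    malformed = sum(malformed),
    removed_low_quality = tab$low_quality,
    removed_adapter_artifact = tab$`5p_only` + tab$both_no_insert + tab$none,
    adapter_subcounts = list(five_prime = tab$`5p_only`,
                             no_insert = tab$both_no_insert,
                             no_3p_adapter = tab$none),
    removed_polyA = tab$polyA,
    removed_short = tab$short,
    clean = tab$`3p_only`
  ), class = "qc_report")
  list(reads = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report: total", x$total_raw, "clean", x$clean, "\n")
  for (f in setdiff(names(x), c("total_raw", "clean", "adapter_subcounts"))) {
    cat(" ", f, x[[f]], "\n")
  }
  invisible(x)
}

#' Flatten a QC report to a one-row data frame
#' @param report a `qc_report`.
#' @export
qc_report_df <- function(report) {
  flat <- unclass(report)
  sub <- flat$adapter_subcounts
  flat$adapter_subcounts <- NULL
  out <- as.data.frame(flat)
  if (!is.null(sub)) {
    out <- cbind(out, as.data.frame(stats::setNames(
      sub, paste0("adapter_", names(sub)))))
  }
  out
}

#' Write a QC report as TSV and JSON
#' @param report a `qc_report`; `prefix` output path prefix.
#' @export
write_qc_report <- function(report, prefix) {
  utils::write.table(qc_report_df(report), paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report), paste0(prefix, ".json"),
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' Clean paired mRNA reads
#'
#' Adapter-trims both mates, then drops a pair when either mate is shorter
#' than `min_len` after trimming, has more than `max_n_frac` N bases, or
#' more than `max_lowq_frac` bases at Phred <= 20.
#'
#' @param r1,r2 data.frames with `id`, `seq`, `qual`; mates are matched by
#'   `id`. Unmatched ids are counted as malformed and dropped.
#' @param adapter adapter sequence to trim from the 3' end.
#' @param min_len minimum post-trim length (50).
#' @param max_n_frac maximum N fraction (0.10).
#' @param max_lowq_frac maximum fraction of Phred <= 20 bases (0.50).
#' @return list with `r1`, `r2` (cleaned pairs) and `report`.
#' @export
clean_mrna_reads <- function(r1, r2, adapter, min_len = 50L,
                             max_n_frac = 0.10, max_lowq_frac = 0.50) {
  common <- intersect(r1$id, r2$id)
  orphan <- (nrow(r1) - length(common)) + (nrow(r2) - length(common))
  if (orphan > 0) message(orphan, " orphan mates dropped")
  r1 <- r1[match(common, r1$id), , drop = FALSE]
  r2 <- r2[match(common, r2$id), , drop = FALSE]
  total <- length(common) + orphan

  trim <- function(r) {
    bad <- nchar(r$seq) != nchar(r$qual)
    r$seq[bad] <- ""
    p <- find_adapter(r$seq, adapter)
    cut <- !is.na(p)
    r$seq[cut] <- substr(r$seq[cut], 1L, p[cut] - 1L)
    r$qual[cut] <- substr(r$qual[cut], 1L, p[cut] - 1L)
    r$qual <- substr(r$qual, 1L, nchar(r$seq))
    r
  }
  r1 <- trim(r1)
  r2 <- trim(r2)

  len_ok <- nchar(r1$seq) >= min_len & nchar(r2$seq) >= min_len
  nfrac <- function(r) count_chars(r$seq, "N", fixed = TRUE) /
    pmax(nchar(r$seq), 1L)
  n_ok <- nfrac(r1) <= max_n_frac & nfrac(r2) <= max_n_frac
  lfrac <- function(r) count_chars(r$qual, PHRED20_CLASS) /
    pmax(nchar(r$qual), 1L)
  q_ok <- lfrac(r1) <= max_lowq_frac & lfrac(r2) <= max_lowq_frac

  cat_pair <- ifelse(!len_ok, "short",
                     ifelse(!n_ok, "N", ifelse(!q_ok, "low_quality",
                                               "clean")))
  keep <- cat_pair == "clean"
  report <- structure(list(
    total_raw = total,
    malformed = orphan,
    removed_short = sum(cat_pair == "short"),
    removed_N = sum(cat_pair == "N"),
    removed_low_quality = sum(cat_pair == "low_quality"),
    clean = sum(keep)
  ), class = "qc_report")
  list(r1 = r1[keep, , drop = FALSE], r2 = r2[keep, , drop = FALSE],
       report = report)
}
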