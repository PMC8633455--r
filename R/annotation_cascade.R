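## Tag collapsing and the annotation cascade. Clean reads are collapsed to
## distinct sequences ("tags") carrying per-library abundance counts, then
## each tag is assigned exactly one category by a fixed precedence order:
## rRNA, snRNA, snoRNA, tRNA, repeat, miRNA catalogue, exon (sense /
## antisense), intron (sense / antisense), unannotated. Matching is exact
## full-length substring matching (sense-only against the structural-RNA
## reference sets, both strands against the genome), standing in for
## zero-mismatch short-read alignment.

CATEGORY_LEVELS <- c("rRNA", "snRNA", "snoRNA", "tRNA", "repeat", "miRNA",
                     "exon_sense", "exon_antisense", "intron_sense",
                     "intron_antisense", "unannotated")

#' Collapse cleaned reads into a tag table
#'
#' @param reads_by_library named list (library id -> data.frame with `seq`,
#'   or a character vector of sequences).
#' @return data.frame with column `seq` followed by one integer count
#'   column per library, rows sorted by sequence so the result is
#'   independent of read order.
#' @export
collapse_tags <- function(reads_by_library) {
  stopifnot(length(names(reads_by_library)) == length(reads_by_library))
  libs <- names(reads_by_library)
  dts <- lapply(libs, function(l) {
    x <- reads_by_library[[l]]
    s <- if (is.data.frame(x)) x$seq else x
    if (!length(s)) return(NULL)
    data.table::data.table(seq = s, lib = l)
  })
  dt <- data.table::rbindlist(dts)
  if (!nrow(dt)) {
    out <- data.frame(seq = character(0))
    for (l in libs) out[[l]] <- integer(0)
    return(out)
  }
  cnt <- dt[, .N, by = c("seq", "lib")]
  wide <- data.table::dcast(cnt, seq ~ lib, value.var = "N", fill = 0L)
  missing <- setdiff(libs, colnames(wide))
  for (l in missing) wide[[l]] <- 0L
  wide <- wide[order(wide$seq), c("seq", libs), with = FALSE]
  as.data.frame(wide)
}

#' Count matrix of a tag table
#' @param tags tag table from [collapse_tags()].
#' @export
tag_counts <- function(tags) {
  m <- as.matrix(tags[, setdiff(colnames(tags), "seq"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tags$seq
  m
}

## which tags occur as a (sense) substring of any sequence in `refs`;
## returns, for each tag, the name of the first matching reference or NA
substring_hits <- function(tag_seqs, refs) {
  out <- rep(NA_character_, length(tag_seqs))
  if (!length(tag_seqs) || !length(refs)) return(out)
  subject <- Biostrings::DNAStringSet(refs)
  widths <- nchar(tag_seqs)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tag_seqs[idx]))
    hits <- Biostrings::vwhichPDict(pd, subject)
    for (s in seq_along(hits)) {
      h <- hits[[s]]
      h <- h[is.na(out[idx[h]])]
      out[idx[h]] <- names(refs)[s]
    }
  }
  out
}

#' Exact genome hits of a set of tags (both strands)
#'
#' @param tag_seqs character vector of tag sequences (DNA).
#' @param genome named character vector of chromosome sequences.
#' @return data.frame (seq, seqid, start, end, strand), ordered by
#'   (seqid, start); a minus-strand hit means the tag matches the reverse
#'   complement of the plus strand at that interval.
#' @export
genome_hits <- function(tag_seqs, genome) {
  res <- list()
  if (!length(tag_seqs)) {
    return(data.frame(seq = character(0), seqid = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  widths <- nchar(tag_seqs)
  for (chr in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chr]])
    for (w in sort(unique(widths))) {
      idx <- which(widths == w)
      for (str in c("+", "-")) {
        pats <- if (str == "+") tag_seqs[idx] else revcomp(tag_seqs[idx])
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
        mi <- Biostrings::matchPDict(pd, subj)
        nh <- S4Vectors::elementNROWS(mi)
        if (!sum(nh)) next
        which_pat <- rep(idx, nh)
        ir <- unlist(mi)
        res[[length(res) + 1L]] <- data.frame(
          seq = tag_seqs[which_pat], seqid = chr,
          start = IRanges::start(ir), end = IRanges::end(ir), strand = str,
          row.names = NULL)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(seq = character(0), seqid = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$seqid, out$start, out$end, out$strand), , drop = FALSE]
}

#' Classify tags into annotation categories
#'
#' @param tags tag table from [collapse_tags()] (or data.frame with `seq`).
#' @param refs reference bundle: list with `ncrna` (named list of named
#'   character vectors: rRNA, snRNA, snoRNA, tRNA), `genome`, `repeats`
#'   (data.frame seqid/start/end), `gff` (gene table, see [read_gff3()])
#'   and `catalogue` (list with `mature` data.frame having `name`, `seq`).
#' @param precedence category order; the first matching class wins.
#' @return data.frame (seq, category, evidence).
#' @export
classify_tags <- function(tags, refs,
                          precedence = c("rRNA", "snRNA", "snoRNA", "tRNA",
                                         "repeat", "miRNA", "exon_sense",
                                         "exon_antisense", "intron_sense",
                                         "intron_antisense")) {
  seqs <- tags$seq
  n <- length(seqs)
  category <- rep(NA_character_, n)
  evidence <- rep(NA_character_, n)
  ncrna_classes <- c("rRNA", "snRNA", "snoRNA", "tRNA")
  for (cl in ncrna_classes) {
    if (is.null(refs$ncrna[[cl]])) {
      stop("reference bundle is missing the ", cl, " class")
    }
  }

  assign_cat <- function(cat, hit_idx, ev) {
    mask <- is.na(category[hit_idx])
    open <- hit_idx[mask]
    category[open] <<- cat
    evidence[open] <<- ev[mask]
    invisible(NULL)
  }

  ## pattern dictionaries are built once per tag width and reused for
  ## every reference class and the genome
  groups <- split(seq_len(n), nchar(seqs))
  pds <- lapply(groups, function(idx) {
    Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
  })
  match_class <- function(refs_named) {
    out <- rep(NA_character_, n)
    subject <- Biostrings::DNAStringSet(refs_named)
    for (g in seq_along(groups)) {
      hits <- Biostrings::vwhichPDict(pds[[g]], subject)
      for (s in seq_along(hits)) {
        h <- groups[[g]][hits[[s]]]
        h <- h[is.na(out[h])]
        out[h] <- names(refs_named)[s]
      }
    }
    out
  }

  ## structural RNA classes (sense-only substring match)
  for (cl in intersect(precedence, ncrna_classes)) {
    hit <- match_class(refs$ncrna[[cl]])
    idx <- which(!is.na(hit))
    if (length(idx)) assign_cat(cl, idx, hit[idx])
  }

  ## genome hits for everything still open; minus-strand hits are found
  ## by matching the same dictionaries against the reverse-complemented
  ## chromosome and mapping coordinates back
  gh_list <- list()
  for (chr in names(refs$genome)) {
    glen <- nchar(refs$genome[[chr]])
    subj_fwd <- Biostrings::DNAString(refs$genome[[chr]])
    subj_rev <- Biostrings::DNAString(revcomp(refs$genome[[chr]]))
    for (g in seq_along(groups)) {
      for (str in c("+", "-")) {
        mi <- Biostrings::matchPDict(pds[[g]],
                                     if (str == "+") subj_fwd else subj_rev)
        nh <- S4Vectors::elementNROWS(mi)
        if (!sum(nh)) next
        which_tag <- rep(groups[[g]], nh)
        ir <- unlist(mi)
        st <- IRanges::start(ir)
        en <- IRanges::end(ir)
        if (str == "-") {
          tmp <- glen - en + 1L
          en <- glen - st + 1L
          st <- tmp
        }
        gh_list[[length(gh_list) + 1L]] <- data.frame(
          seq = seqs[which_tag], seqid = chr, start = st, end = en,
          strand = str, row.names = NULL)
      }
    }
  }
  gh <- if (length(gh_list)) {
    x <- do.call(rbind, gh_list)
    x[order(x$seqid, x$start, x$end, x$strand), , drop = FALSE]
  } else {
    data.frame(seq = character(0), seqid = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  }
  ## first hit per tag by (seqid, start)
  first_hit <- gh[!duplicated(gh$seq), , drop = FALSE]

  ghr <- GenomicRanges::GRanges(gh$seqid, IRanges::IRanges(gh$start, gh$end),
                                strand = gh$strand)
  ## repeats (either strand)
  if (!is.null(refs$repeats) && nrow(refs$repeats)) {
    rep_gr <- GenomicRanges::GRanges(
      refs$repeats$seqid, IRanges::IRanges(refs$repeats$start,
                                           refs$repeats$end))
    ov <- GenomicRanges::findOverlaps(ghr, rep_gr, ignore.strand = TRUE)
    rep_seqs <- unique(gh$seq[S4Vectors::queryHits(ov)])
    idx <- which(seqs %in% rep_seqs)
    if (length(idx) && "repeat" %in% precedence) {
      assign_cat("repeat", idx, rep("repeat_region", length(idx)))
    }
  }

  ## miRNA catalogue (exact full-length match, DNA form)
  cat_mat <- as_dna(refs$catalogue$mature$seq)
  mi <- match(seqs, cat_mat)
  idx <- which(!is.na(mi))
  if (length(idx) && "miRNA" %in% precedence) {
    assign_cat("miRNA", idx, refs$catalogue$mature$name[mi[idx]])
  }

  ## exon / intron classes from gene models
  gff <- refs$gff
  genes <- gff[gff$type == "gene", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  gene_strand <- stats::setNames(genes$strand, genes$ID)
  exon_gr <- GenomicRanges::GRanges(exons$seqid,
                                    IRanges::IRanges(exons$start, exons$end))
  gene_gr <- GenomicRanges::GRanges(genes$seqid,
                                    IRanges::IRanges(genes$start, genes$end))
  ov_ex <- GenomicRanges::findOverlaps(ghr, exon_gr, ignore.strand = TRUE)
  ov_gn <- GenomicRanges::findOverlaps(ghr, gene_gr, ignore.strand = TRUE)

  hit_class <- function(ov, feat_parent, feat_strand, kind) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    sense <- gh$strand[qh] == feat_strand[sh]
    list(
      sense = data.frame(seq = gh$seq[qh][sense], ev = feat_parent[sh][sense]),
      anti = data.frame(seq = gh$seq[qh][!sense], ev = feat_parent[sh][!sense])
    )
  }
  ex <- hit_class(ov_ex, exons$Parent, gene_strand[exons$Parent], "exon")
  gn <- hit_class(ov_gn, genes$ID, genes$strand, "gene")

  for (spec1 in list(list("exon_sense", ex$sense),
                     list("exon_antisense", ex$anti),
                     list("intron_sense", gn$sense),
                     list("intron_antisense", gn$anti))) {
    cat_name <- spec1[[1]]
    df <- spec1[[2]]
    if (!nrow(df) || !(cat_name %in% precedence)) next
    df <- df[!duplicated(df$seq), , drop = FALSE]
    idx <- match(df$seq, seqs)
    assign_cat(cat_name, idx, df$ev)
  }

  ## remaining tags with or without genome hits -> unannotated
  left <- which(is.na(category))
  category[left] <- "unannotated"
  loc <- first_hit[match(seqs[left], first_hit$seq), , drop = FALSE]
  evidence[left] <- ifelse(is.na(loc$seqid), NA,
                           paste0(loc$seqid, ":", loc$start, "-", loc$end,
                                  "(", loc$strand, ")"))
  data.frame(seq = seqs,
             category = factor(category, levels = CATEGORY_LEVELS),
             evidence = evidence, row.names = NULL)
}

#' Abundance-weighted category distribution per library
#'
#' @param tags tag table; `classification` result of [classify_tags()].
#' @return data.frame (library, category, count, percent); per-library
#'   percents sum to 100.
#' @export
category_distribution <- function(tags, classification) {
  counts <- tag_counts(tags)
  stopifnot(nrow(counts) == nrow(classification))
  libs <- colnames(counts)
  out <- list()
  for (l in libs) {
    by_cat <- tapply(counts[, l], classification$category, sum, default = 0L)
    total <- sum(counts[, l])
    out[[l]] <- data.frame(
      library = l, category = names(by_cat),
      count = as.integer(by_cat),
      percent = if (total > 0) 100 * as.numeric(by_cat) / total else 0,
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$category <- factor(res$category, levels = CATEGORY_LEVELS)
  res
}

#' Abundance-weighted length distribution per library
#'
#' @param tags tag table.
#' @param lengths histogram support (default 18-30 nt).
#' @return matrix lengths x libraries of fractions (each column sums to 1
#'   unless a library is empty, which produces zeros and a warning).
#' @export
length_distribution <- function(tags, lengths = 18:30) {
  counts <- tag_counts(tags)
  w <- nchar(tags$seq)
  out <- matrix(0, nrow = length(lengths), ncol = ncol(counts),
                dimnames = list(lengths, colnames(counts)))
  for (l in colnames(counts)) {
    tot <- sum(counts[, l])
    if (tot == 0) {
      warning("library ", l, " is empty")
      next
    }
    by_len <- tapply(counts[, l], factor(w, levels = lengths), sum,
                     default = 0L)
    out[, l] <- as.numeric(by_len) / tot
  }
  out
}
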