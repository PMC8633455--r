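## Known-miRNA assignment and novel hairpin prediction.
##
## Known assignment: a tag identical to a focal-species catalogue mature is
## an "existing" miRNA (named with -5p/-3p by precursor arm); a tag
## matching only another species' mature is "conserved" (renamed with
## -x/-y by arm). Novel prediction follows the MIREAP-style criteria:
## mature 18-25 nt, star 20-23 nt, <= 20 genome copies, precursor
## MFE <= -18 kcal/mol, mature/star spacing 16-300 nt, duplex bulges
## <= 4 nt, duplex asymmetry <= 4 nt, 20-nt precursor flanks, and a single
## stem-loop with the mature on one arm. The star is the Dicer partner of
## the mature with 2-nt 3' overhangs, derived from the folded structure.

#' Structural criteria for novel miRNA prediction
#'
#' @param mature_len,star_len inclusive length bounds (nt).
#' @param max_copies maximum genome copy number of the mature tag.
#' @param precursor_mfe_max maximum (i.e. most positive) allowed precursor
#'   MFE in kcal/mol; hairpins must fold at least this stably.
#' @param space inclusive bounds on the unpaired gap between mature and
#'   star (nt).
#' @param max_bulge largest unpaired run inside the mature/star duplex.
#' @param max_asym maximum |unpaired on mature arm - unpaired on star arm|
#'   inside the duplex.
#' @param flank precursor flank excised on each side (nt).
#' @param min_partner_frac minimum fraction of mature positions that must
#'   find a complementary partner when scanning for the star region.
#' @export
mireap_params <- function(mature_len = c(18L, 25L), star_len = c(20L, 23L),
                          max_copies = 20L, precursor_mfe_max = -18,
                          space = c(16L, 300L), max_bulge = 4L,
                          max_asym = 4L, flank = 20L,
                          min_partner_frac = 0.6) {
  list(mature_len = mature_len, star_len = star_len,
       max_copies = max_copies, precursor_mfe_max = precursor_mfe_max,
       space = space, max_bulge = max_bulge, max_asym = max_asym,
       flank = flank, min_partner_frac = min_partner_frac)
}

## pairing partner of every position, 0 when unpaired
partner_vector <- function(db) {
  pr <- db_pairs(db)
  n <- nchar(db)
  p <- integer(n)
  if (nrow(pr)) {
    p[pr[, 1]] <- pr[, 2]
    p[pr[, 2]] <- pr[, 1]
  }
  p
}

## Derive the star interval from a folded precursor: partner of the
## mature's paired ends extrapolated over unpaired terminal bases, shifted
## by the 2-nt 3' overhang of Dicer processing.
derive_star <- function(fold, mstart, mend) {
  p <- partner_vector(fold$structure)
  mpos <- mstart:mend
  paired <- mpos[p[mpos] > 0]
  if (length(paired) < 2) return(NULL)
  q1 <- paired[1]
  q2 <- paired[length(paired)]
  star_end <- p[q1] + (q1 - mstart) + 2L
  star_start <- p[q2] - (mend - 2L - q2)
  n <- nchar(fold$seq)
  if (star_start < 1L || star_end > n || star_start >= star_end) return(NULL)
  ## star must not overlap the mature
  if (star_start <= mend && star_end >= mstart) return(NULL)
  c(star_start, star_end)
}

## duplex geometry between mature and star: largest unpaired run (bulge)
## and the asymmetry of unpaired counts between the two sides
duplex_geometry <- function(fold, mstart, mend) {
  p <- partner_vector(fold$structure)
  mpos <- mstart:mend
  paired <- mpos[p[mpos] > 0]
  if (length(paired) < 2) {
    return(list(bulge = Inf, asym = Inf))
  }
  gaps_m <- diff(paired) - 1L
  gaps_s <- abs(diff(p[paired])) - 1L
  ## unpaired mature bases at the ends count toward the mature side
  end_unpaired <- (paired[1] - mstart) + (mend - paired[length(paired)])
  list(bulge = max(c(gaps_m, gaps_s, 0L)),
       asym = abs(sum(gaps_m) + end_unpaired - sum(gaps_s)))
}

#' Evaluate all structural criteria for a candidate precursor
#'
#' Re-derives every criterion from the precursor sequence and the mature
#' position alone: folds the precursor, derives the star, measures the
#' duplex geometry and checks the bounds in `params`.
#'
#' @param precursor_seq precursor sequence (RNA or DNA).
#' @param mature_seq mature sequence; must occur in the precursor.
#' @param copies genome copy number of the mature (external information).
#' @param params [mireap_params()].
#' @param par folding energy parameters.
#' @return list with `pass` (all criteria), the individual criterion flags,
#'   and the measured values (mfe, star_seq, space, bulge, asym, arm,
#'   structure).
#' @export
validate_hairpin <- function(precursor_seq, mature_seq, copies = 1L,
                             params = mireap_params(),
                             par = energy_parameters()) {
  prec <- as_rna(precursor_seq)
  mat <- as_rna(mature_seq)
  f <- rna_fold(prec, par)
  mstart <- regexpr(mat, prec, fixed = TRUE)[1]
  if (mstart < 0) stop("mature sequence not found in precursor")
  mend <- mstart + nchar(mat) - 1L
  m <- nchar(mat)

  crit <- list(mature_min = m >= params$mature_len[1],
               mature_max = m <= params$mature_len[2],
               copies = copies <= params$max_copies,
               mfe = f$mfe <= params$precursor_mfe_max)
  sl <- is_stemloop(f, mat)
  crit$stemloop <- sl$ok
  star <- derive_star(f, mstart, mend)
  if (is.null(star)) {
    crit[c("star_min", "star_max", "space_min", "space_max", "bulge",
           "asym")] <- FALSE
    vals <- list(star_seq = NA, space = NA, bulge = NA, asym = NA)
  } else {
    star_len <- star[2] - star[1] + 1L
    space <- if (star[1] > mend) star[1] - mend - 1L else mstart - star[2] - 1L
    geo <- duplex_geometry(f, mstart, mend)
    crit$star_min <- star_len >= params$star_len[1]
    crit$star_max <- star_len <= params$star_len[2]
    crit$space_min <- space >= params$space[1]
    crit$space_max <- space <= params$space[2]
    crit$bulge <- geo$bulge <= params$max_bulge
    crit$asym <- geo$asym <= params$max_asym
    vals <- list(star_seq = substr(prec, star[1], star[2]),
                 space = space, bulge = geo$bulge, asym = geo$asym)
  }
  c(list(pass = all(unlist(crit)), criteria = crit,
         mfe = f$mfe, structure = f$structure, arm = sl$arm,
         mature_start = mstart, mature_end = mend),
    vals)
}

#' Assign tags to known (existing or conserved) miRNAs
#'
#' @param tags tag table from [collapse_tags()].
#' @param catalogue list with `mature` (data.frame: `name`, `seq` (RNA),
#'   `precursor`, `focal` logical) and `hairpin` (named character, RNA).
#' @param par folding parameters (used to place catalogue matures on an
#'   arm of their precursor).
#' @return list with `info` (data.frame: name, status, arm, mature,
#'   precursor, tag_seq) and `counts` (matrix, rows matching `info`).
#' @export
assign_known <- function(tags, catalogue, par = energy_parameters()) {
  if (is.null(catalogue$mature) || !nrow(catalogue$mature)) {
    stop("empty miRNA catalogue")
  }
  mat <- catalogue$mature
  mat$dna <- as_dna(mat$seq)
  counts <- tag_counts(tags)

  arm_cache <- new.env(parent = emptyenv())
  arm_of <- function(mature_rna, precursor_name) {
    key <- paste0(precursor_name, "|", mature_rna)
    if (!is.null(arm_cache[[key]])) return(arm_cache[[key]])
    prec <- if (!is.null(precursor_name) &&
                precursor_name %in% names(catalogue$hairpin)) {
      catalogue$hairpin[[precursor_name]]
    } else {
      NULL
    }
    arm <- "5p"
    if (!is.null(prec)) {
      pos <- regexpr(as_rna(mature_rna), as_rna(prec), fixed = TRUE)[1]
      if (pos > 0) {
        sl <- tryCatch(is_stemloop(rna_fold(as_rna(prec), par), mature_rna),
                       error = function(e) list(ok = FALSE, arm = "none"))
        if (sl$ok) {
          arm <- sl$arm
        } else {
          ## midpoint fallback for precursors that do not fold cleanly
          arm <- if (pos + nchar(mature_rna) / 2 <= nchar(prec) / 2) "5p"
                 else "3p"
        }
      }
    }
    arm_cache[[key]] <- arm
    arm
  }

  rows <- list()
  for (i in seq_len(nrow(tags))) {
    hit <- which(mat$dna == tags$seq[i])
    if (!length(hit)) next
    ## focal species beats other species; alphabetical name within a tier
    hit <- hit[order(!mat$focal[hit], mat$name[hit])]
    h <- hit[1]
    arm <- arm_of(mat$seq[h], mat$precursor[h])
    if (mat$focal[h]) {
      status <- "existing"
      name <- mat$name[h]
      if (!grepl("-(5p|3p)$", name)) name <- paste0(name, "-", arm)
      arm_label <- arm
    } else {
      status <- "conserved"
      base <- sub("^[a-z]{3,4}-", "", mat$name[h])
      base <- sub("-(5p|3p)$", "", base)
      arm_label <- if (arm == "5p") "x" else "y"
      name <- paste0(base, "-", arm_label)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, status = status, arm = arm_label,
      mature = as_rna(tags$seq[i]), precursor = mat$precursor[h],
      tag_seq = tags$seq[i], row.names = NULL)
  }
  if (!length(rows)) {
    return(list(info = data.frame(name = character(0), status = character(0),
                                  arm = character(0), mature = character(0),
                                  precursor = character(0),
                                  tag_seq = character(0)),
                counts = counts[integer(0), , drop = FALSE]))
  }
  info <- do.call(rbind, rows)
  list(info = info, counts = counts[match(info$tag_seq, tags$seq), ,
                                    drop = FALSE])
}

#' Predict novel miRNA hairpins from unannotated tags
#'
#' For every perfect genome hit of an unannotated tag, both arm hypotheses
#' are examined: the star region is searched by complementarity up to the
#' maximum mature/star spacing on either side, a precursor with 20-nt
#' flanks is excised and folded, and all structural criteria are checked.
#' The first passing window by genomic coordinate is kept per locus.
#'
#' @param tags tag table of the unannotated pool.
#' @param genome named character vector of chromosome sequences.
#' @param params [mireap_params()].
#' @param par folding parameters.
#' @return data.frame of evaluated candidates with per-criterion columns
#'   and a `pass` flag (one row per tag/locus combination that yielded a
#'   foldable window; tags whose copy number exceeds the bound produce a
#'   single failing row).
#' @export
predict_novel <- function(tags, genome, params = mireap_params(),
                          par = energy_parameters()) {
  seqs <- tags$seq
  counts <- tag_counts(tags)
  hits <- genome_hits(seqs, genome)
  copies <- table(hits$seq)
  out <- list()

  emit <- function(tag, locus, val, copies_n) {
    cr <- val$criteria
    out[[length(out) + 1L]] <<- data.frame(
      tag = tag, seqid = locus[1], start = as.integer(locus[2]),
      end = as.integer(locus[3]), strand = locus[4],
      precursor = val$precursor, structure = val$structure,
      mfe = val$mfe, star_seq = val$star_seq, arm = val$arm,
      space = val$space, bulge = val$bulge, asym = val$asym,
      copies = copies_n,
      c_mature_min = cr$mature_min, c_mature_max = cr$mature_max,
      c_star_min = isTRUE(cr$star_min), c_star_max = isTRUE(cr$star_max),
      c_copies = cr$copies, c_mfe = cr$mfe,
      c_space_min = isTRUE(cr$space_min),
      c_space_max = isTRUE(cr$space_max),
      c_bulge = isTRUE(cr$bulge), c_asym = isTRUE(cr$asym),
      c_stemloop = cr$stemloop,
      pass = val$pass, row.names = NULL)
  }

  rc_cache <- new.env(parent = emptyenv())
  for (tag in unique(hits$seq)) {
    m <- nchar(tag)
    if (m < params$mature_len[1] || m > params$mature_len[2]) next
    n_cop <- as.integer(copies[[tag]])
    th <- hits[hits$seq == tag, , drop = FALSE]
    for (r in seq_len(nrow(th))) {
      ## over-copied tags are rejected; one recorded row is enough
      if (n_cop > params$max_copies && r > 1L) break
      chrseq <- genome[[th$seqid[r]]]
      glen <- nchar(chrseq)
      ## work in the coordinate system of the tag's strand
      if (th$strand[r] == "+") {
        strand_seq <- chrseq
        s_start <- th$start[r]
      } else {
        key <- th$seqid[r]
        if (is.null(rc_cache[[key]])) rc_cache[[key]] <- revcomp(chrseq)
        strand_seq <- rc_cache[[key]]
        s_start <- glen - th$end[r] + 1L
      }
      s_end <- s_start + m - 1L
      for (side in c("right", "left")) {
        cand <- excise_candidate(strand_seq, s_start, s_end, tag, side,
                                 params)
        if (is.null(cand)) next
        val <- validate_hairpin(cand$precursor, tag, n_cop, params, par)
        locus <- strand_coords(th[r, ], cand, glen)
        emit(tag, locus, c(val, list(precursor = cand$precursor)), n_cop)
        if (val$pass) break
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag = character(0), pass = logical(0)))
  }
  res <- do.call(rbind, out)
  attr(res, "counts") <- counts
  res
}

## map a candidate window (in strand coordinates) back to plus-strand
## genomic coordinates
strand_coords <- function(hit, cand, glen) {
  if (hit$strand == "+") {
    c(hit$seqid, cand$w_start, cand$w_end, "+")
  } else {
    c(hit$seqid, glen - cand$w_end + 1L, glen - cand$w_start + 1L, "-")
  }
}

## Excise a candidate precursor around a mature hit: scan for the most
## complementary star placement within the allowed spacing on the given
## side, then cut mature/star plus flanks.
excise_candidate <- function(strand_seq, s_start, s_end, tag, side, params) {
  m <- nchar(tag)
  glen <- nchar(strand_seq)
  gmin <- params$space[1]
  gmax <- params$space[2]
  tagv <- strsplit(as_rna(tag), "")[[1]]
  ## expected star (perfect Dicer partner): star[j] pairs mature[m-1-j]
  can_pair <- function(a, b) {
    (a == "A" & b == "U") | (a == "U" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G") |
      (a == "G" & b == "U") | (a == "U" & b == "G")
  }
  best <- NULL
  if (side == "right") {
    lo <- s_end + 1L + gmin
    hi <- min(s_end + 1L + gmax, glen - m + 1L)
  } else {
    lo <- max(1L, s_start - gmax - m)
    hi <- s_start - gmin - m
  }
  if (lo > hi) return(NULL)
  region <- as_rna(substr(strand_seq, lo, hi + m - 1L))
  rv <- strsplit(region, "")[[1]]
  npos <- hi - lo + 1L
  score <- numeric(npos)
  for (j in 1:(m - 2L)) {
    idx <- seq_len(npos) + j - 1L
    score <- score + can_pair(rv[idx], tagv[m - 1L - j + 0L])
  }
  ok <- which(score >= params$min_partner_frac * (m - 2L))
  if (!length(ok)) return(NULL)
  best_off <- ok[which.max(score[ok])]
  star_start <- lo + best_off - 1L
  star_end <- star_start + m - 1L
  w_start <- max(1L, min(s_start, star_start) - params$flank)
  w_end <- min(glen, max(s_end, star_end) + params$flank)
  prec <- as_rna(substr(strand_seq, w_start, w_end))
  ## the mature must occur in the window (it does by construction)
  list(precursor = prec, w_start = w_start, w_end = w_end)
}

#' Collapse passing hairpin candidates into named novel miRNA records
#'
#' Candidates sharing a mature sequence collapse to one record, named
#' `novel-mNNNN-<arm>` in order of descending total count, ties broken by
#' sequence.
#'
#' @param cands result of [predict_novel()] (its `pass` rows are used).
#' @param tags tag table supplying the counts.
#' @return list with `info` and `counts` as in [assign_known()], plus a
#'   `loci` data.frame mapping records to genomic loci.
#' @export
dedupe_candidates <- function(cands, tags) {
  counts <- tag_counts(tags)
  pass <- cands[cands$pass, , drop = FALSE]
  if (!nrow(pass)) {
    return(list(info = data.frame(name = character(0), status = character(0),
                                  arm = character(0), mature = character(0),
                                  precursor = character(0),
                                  tag_seq = character(0)),
                counts = counts[integer(0), , drop = FALSE],
                loci = pass))
  }
  mats <- unique(pass$tag)
  tot <- rowSums(counts)[mats]
  tot[is.na(tot)] <- 0
  ord <- order(-tot, mats)
  mats <- mats[ord]
  info <- data.frame(
    name = character(length(mats)), status = "novel",
    arm = character(length(mats)), mature = as_rna(mats),
    precursor = character(length(mats)), tag_seq = mats,
    copies_on_reference = integer(length(mats)), row.names = NULL)
  for (i in seq_along(mats)) {
    rows <- pass[pass$tag == mats[i], , drop = FALSE]
    arm <- rows$arm[1]
    info$name[i] <- sprintf("novel-m%04d-%s", i, arm)
    info$arm[i] <- arm
    info$precursor[i] <- rows$precursor[1]
    info$copies_on_reference[i] <- nrow(rows)
  }
  list(info = info,
       counts = counts[match(mats, rownames(counts)), , drop = FALSE],
       loci = pass)
}
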