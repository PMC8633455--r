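## Synthetic study generator. Emulates a three-stage (PS/TS/SS), three
## replicate stem small-RNA + mRNA experiment at toy scale: a repeat- and
## gene-bearing genome with planted miRNA hairpin loci, a miRBase-style
## catalogue split into focal and other species, structural-RNA reference
## sets, nine adapter-carrying FASTQ libraries with planted QC failures,
## a gene count matrix with planted stage effects, planted target sites
## obeying the duplex rules by construction, and planted negatively
## correlated miRNA-target pairs. Everything is returned with ground
## truth so downstream stages can be scored.

local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Defaults describe the emulated study: 9 libraries (3 stages x 3
#' replicates), 200,000 reads per library, 8 planted novel hairpin loci,
#' a 30-entry miRNA catalogue, a 100-kb genome with 120 two-exon genes,
#' an 8-fold (log2FC = 3) planted stage effect and NB dispersion 0.05.
#'
#' @param seed integer seed driving every random draw.
#' @param genome_length genome size in bases.
#' @param n_known_mirnas catalogue size (half focal species, half other).
#' @param n_novel_hairpins hairpin loci planted in the genome.
#' @param n_genes number of two-exon genes.
#' @param stages three stage labels, developmental order.
#' @param replicates_per_stage libraries per stage.
#' @param library_depth reads per sRNA library.
#' @param adapter_3p,adapter_5p adapter sequences appended to inserts.
#' @param effect_log2fc planted differential-expression magnitude.
#' @param n_de_mirnas number of miRNAs given a stage effect.
#' @param negcorr_fraction fraction of planted miRNA-target pairs whose
#'   target is anti-regulated (negatively correlated).
#' @param nb_dispersion negative-binomial dispersion of all counts.
#' @param mrna_depth fragments per mRNA library.
#' @param n_extra_degs additional DE genes without miRNA coupling.
#' @param targets_per_mirna planted target genes per DE miRNA.
#' @param star_fraction star-strand read abundance relative to the mature.
#' @param contaminant_mix named proportions over read classes (must
#'   include `mirna` and sum to 1).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_known_mirnas = 30L,
                       n_novel_hairpins = 8L,
                       n_genes = 120L,
                       stages = c("PS", "TS", "SS"),
                       replicates_per_stage = 3L,
                       library_depth = 200000L,
                       adapter_3p = "AGATCGGAAGAGCACACGTCT",
                       adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                       effect_log2fc = 3,
                       n_de_mirnas = 12L,
                       negcorr_fraction = 0.8,
                       nb_dispersion = 0.05,
                       mrna_depth = 300000L,
                       n_extra_degs = 8L,
                       targets_per_mirna = 2L,
                       star_fraction = 0.04,
                       contaminant_mix = c(rRNA = 0.06, tRNA = 0.03,
                                           snRNA = 0.015, snoRNA = 0.015,
                                           `repeat` = 0.02,
                                           degradation = 0.04,
                                           polyA = 0.01, short = 0.01,
                                           mirna = 0.80)) {
  if (!"mirna" %in% names(contaminant_mix)) {
    stop("contaminant_mix must include a 'mirna' proportion")
  }
  if (abs(sum(contaminant_mix) - 1) > 1e-9) {
    stop("contaminant and miRNA proportions must sum to 1")
  }
  stopifnot(length(stages) == 3, nb_dispersion > 0,
            negcorr_fraction >= 0, negcorr_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Stage comparisons in developmental order (later over earlier)
#' @param stages stage labels.
#' @export
stage_comparisons <- function(stages = c("PS", "TS", "SS")) {
  list(c(stages[1], stages[2]), c(stages[1], stages[3]),
       c(stages[2], stages[3]))
}

## hairpin construction: star[1..m-2] = revcomp(mature[1..m-2]) pairs the
## mature leaving 2-nt 3' overhangs on both strands
build_hairpin_block <- function(mature_dna, arm, gap_len, flank = 20L) {
  m <- nchar(mature_dna)
  star_core <- revcomp(substr(mature_dna, 1L, m - 2L))
  star <- paste0(star_core, random_dna(2L, c("A", "C")))
  gap <- random_dna(gap_len, c("A", "C"))
  fl <- random_dna(flank, c("A", "C"))
  fr <- random_dna(flank, c("A", "C"))
  core <- if (arm == "5p") paste0(mature_dna, gap, star)
          else paste0(star, gap, mature_dna)
  list(block = paste0(fl, core, fr), star = star,
       mature_offset = if (arm == "5p") flank + 1L
                       else flank + m + gap_len + 1L)
}

bad_mature <- function(seq, config, taken, ncrna_refs) {
  seed3 <- substr(config$adapter_3p, 1, 8)
  seed5 <- substr(config$adapter_5p, 1, 8)
  if (grepl(seed3, seq, fixed = TRUE) || grepl(seed5, seq, fixed = TRUE)) {
    return(TRUE)
  }
  if (seq %in% taken) return(TRUE)
  any(vapply(ncrna_refs, function(refs) {
    any(grepl(seq, refs, fixed = TRUE))
  }, logical(1)))
}

## the mature must occur exactly once in its own hairpin block and not on
## the opposite strand (the gap bases next to the star core can otherwise
## extend the star into a full reverse complement of the mature)
hairpin_block_ok <- function(block, mature) {
  length(gregexpr(mature, block, fixed = TRUE)[[1]]) == 1 &&
    !grepl(revcomp(mature), block, fixed = TRUE)
}

gen_ncrna <- function() {
  mk <- function(k, lens, prefix) {
    stats::setNames(vapply(seq_len(k), function(i) random_dna(lens[i]),
                           character(1)),
                    paste0(prefix, seq_len(k)))
  }
  list(rRNA = mk(2, c(1800L, 900L), "rRNA_"),
       tRNA = mk(8, rep(75L, 8), "tRNA_"),
       snRNA = mk(4, rep(150L, 4), "snRNA_"),
       snoRNA = mk(4, rep(120L, 4), "snoRNA_"))
}

gen_catalogue <- function(config, ncrna, params, par) {
  n <- config$n_known_mirnas
  n_focal <- ceiling(n / 2)
  other_sp <- c("ath", "osa", "zma", "gma", "vvi")
  rows <- list()
  hairpins <- character(0)
  taken <- character(0)
  for (i in seq_len(n)) {
    focal <- i <= n_focal
    arm <- if (i %% 2 == 1) "5p" else "3p"
    for (try in 1:80) {
      m <- sample(20:23, 1)
      mat <- random_dna(m)
      if (bad_mature(mat, config, taken, ncrna)) next
      hp <- build_hairpin_block(mat, arm, sample(16:24, 1))
      if (!hairpin_block_ok(hp$block, mat)) {
        hp <- NULL
        next
      }
      val <- tryCatch(validate_hairpin(hp$block, mat, 1L, params, par),
                      error = function(e) list(pass = FALSE))
      if (isTRUE(val$pass)) break
      hp <- NULL
    }
    if (is.null(hp)) stop("could not construct catalogue hairpin ", i)
    taken <- c(taken, mat)
    if (focal) {
      base <- sprintf("ptc-miR%d%s", 1000 + i, letters[(i %% 3) + 1])
      name <- paste0(base, "-", arm)
      prec <- sub("miR", "MIR", base)
    } else {
      sp <- other_sp[(i %% length(other_sp)) + 1]
      base <- sprintf("%s-miR%d", sp, 2000 + i)
      name <- base
      prec <- sub("miR", "MIR", base)
    }
    rows[[i]] <- data.frame(name = name, seq = as_rna(mat),
                            precursor = prec, focal = focal, arm = arm,
                            dna = mat, row.names = NULL)
    hairpins[prec] <- as_rna(hp$block)
  }
  list(mature = do.call(rbind, rows), hairpin = hairpins)
}

gen_novel <- function(config, ncrna, catalogue, params, par) {
  out <- list()
  taken <- catalogue$mature$dna
  for (i in seq_len(config$n_novel_hairpins)) {
    arm <- if (i %% 2 == 1) "5p" else "3p"
    ok <- FALSE
    for (try in 1:80) {
      mat <- random_dna(21L)
      if (bad_mature(mat, config, taken, ncrna)) next
      hp <- build_hairpin_block(mat, arm, sample(16:24, 1))
      if (!hairpin_block_ok(hp$block, mat)) next
      val <- tryCatch(validate_hairpin(hp$block, mat, 1L, params, par),
                      error = function(e) list(pass = FALSE))
      if (isTRUE(val$pass)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not construct novel hairpin ", i)
    taken <- c(taken, mat)
    out[[i]] <- list(mature = mat, arm = arm, block = hp$block,
                     star = hp$star, mature_offset = hp$mature_offset)
  }
  out
}

gen_genes <- function(config) {
  genes <- list()
  for (i in seq_len(config$n_genes)) {
    e1 <- sample(120:320, 1)
    e2 <- sample(120:320, 1)
    il <- sample(80:220, 1)
    genes[[i]] <- list(id = sprintf("gene%04d", i),
                       strand = sample(c("+", "-"), 1),
                       e1 = e1, e2 = e2, intron_len = il,
                       transcript = random_dna(e1 + e2),
                       intron = random_dna(il))
  }
  genes
}

## place all blocks on one chromosome with random filler between them
assemble_genome <- function(config, genes, novel, n_repeats = 3L) {
  blocks <- list()
  for (g in genes) {
    genomic <- paste0(substr(g$transcript, 1, g$e1), g$intron,
                      substr(g$transcript, g$e1 + 1, g$e1 + g$e2))
    if (g$strand == "-") genomic <- revcomp(genomic)
    blocks[[length(blocks) + 1L]] <- list(type = "gene", id = g$id,
                                          seq = genomic, meta = g)
  }
  for (i in seq_along(novel)) {
    blocks[[length(blocks) + 1L]] <- list(type = "hairpin",
                                          id = paste0("hp", i),
                                          seq = novel[[i]]$block,
                                          meta = novel[[i]])
  }
  rep_seqs <- vapply(seq_len(n_repeats), function(i)
    random_dna(sample(400:600, 1)), character(1))
  for (i in seq_len(n_repeats)) {
    blocks[[length(blocks) + 1L]] <- list(type = "repeat",
                                          id = paste0("rep", i),
                                          seq = rep_seqs[i], meta = NULL)
  }
  blocks <- blocks[sample(length(blocks))]
  blen <- vapply(blocks, function(b) nchar(b$seq), integer(1))
  filler_total <- config$genome_length - sum(blen)
  ngap <- length(blocks) + 1L
  if (filler_total < 30L * ngap) {
    stop("genome_length too small for the requested features")
  }
  w <- runif(ngap)
  gaps <- 30L + floor((filler_total - 30L * ngap) * w / sum(w))
  gaps[ngap] <- filler_total - sum(gaps[-ngap])
  pieces <- character(2L * length(blocks) + 1L)
  coords <- list()
  pos <- 0L
  for (i in seq_along(blocks)) {
    fill <- random_dna(gaps[i])
    pieces[2L * i - 1L] <- fill
    pos <- pos + gaps[i]
    b <- blocks[[i]]
    pieces[2L * i] <- b$seq
    coords[[b$id]] <- list(type = b$type, start = pos + 1L,
                           end = pos + nchar(b$seq), meta = b$meta)
    pos <- pos + nchar(b$seq)
  }
  pieces[2L * length(blocks) + 1L] <- random_dna(gaps[ngap])
  list(genome = c(chr1 = paste(pieces, collapse = "")), coords = coords)
}

gff_from_coords <- function(coords) {
  rows <- list()
  for (id in names(coords)) {
    b <- coords[[id]]
    if (b$type != "gene") next
    g <- b$meta
    gs <- b$start
    ge <- b$end
    if (g$strand == "+") {
      ex <- rbind(c(gs, gs + g$e1 - 1L),
                  c(gs + g$e1 + g$intron_len, ge))
    } else {
      ex <- rbind(c(ge - g$e1 + 1L, ge),
                  c(gs, gs + g$e2 - 1L))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = "chr1", type = c("gene", "exon", "exon"),
      start = c(gs, ex[1, 1], ex[2, 1]), end = c(ge, ex[1, 2], ex[2, 2]),
      strand = g$strand, ID = c(g$id, paste0(g$id, ".e1"),
                                paste0(g$id, ".e2")),
      Parent = c(NA, g$id, g$id), row.names = NULL)
  }
  do.call(rbind, rows)
}

## NB count matrix for the miRNA features across all libraries, with
## per-stage renormalisation so library depth stays near its target
gen_mirna_counts <- function(config, features, alpha, mult, libs, stage_of) {
  p_mi <- config$contaminant_mix[["mirna"]]
  counts <- matrix(0L, nrow = length(features), ncol = length(libs),
                   dimnames = list(features, libs))
  for (l in libs) {
    w <- alpha * mult[, stage_of[[l]]]
    mu <- config$library_depth * p_mi * w / sum(w)
    counts[, l] <- stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion)
  }
  counts
}

draw_fragments <- function(refs, n, lens = 18:28) {
  if (n <= 0) return(character(0))
  ref_idx <- sample(length(refs), n, replace = TRUE,
                    prob = nchar(refs) / sum(nchar(refs)))
  L <- sample(lens, n, replace = TRUE)
  maxstart <- nchar(refs)[ref_idx] - L + 1L
  L[maxstart < 1L] <- 18L
  maxstart <- pmax(1L, nchar(refs)[ref_idx] - L + 1L)
  st <- 1L + floor(runif(n) * maxstart)
  substring(refs[ref_idx], st, st + L - 1L)
}

#' Plant a rule-conforming target site into a gene sequence
#'
#' Builds a site whose brute-force weighted mismatch score equals
#' `weighted_mismatches` exactly: the reverse complement of the miRNA with
#' G:U wobbles (0.5 each) and full mismatches (1 each) introduced at
#' non-adjacent positions outside the 5' half (positions >= 13), which
#' keeps rules 2-5 satisfied by construction. The site overwrites
#' `gene_seq` at `position`.
#'
#' @param mirna miRNA sequence (RNA).
#' @param gene_seq gene (transcript) sequence, DNA.
#' @param weighted_mismatches target score, half-integer in [0, 4].
#' @param position 1-based start of the site window in `gene_seq`.
#' @return modified gene sequence with the planted site attached as
#'   attribute `site`.
#' @export
plant_target_site <- function(mirna, gene_seq, weighted_mismatches,
                              position) {
  w <- weighted_mismatches
  if (w < 0 || w > 4) stop("weighted mismatches exceed the rule 1 cap")
  if (abs(w * 2 - round(w * 2)) > 1e-9) {
    stop("weighted mismatches must be a half-integer")
  }
  mv <- strsplit(as_rna(mirna), "")[[1]]
  L <- length(mv)
  if (position < 1 || position + L - 1 > nchar(gene_seq)) {
    stop("site window outside the gene sequence")
  }
  site <- strsplit(revcomp(paste(mv, collapse = ""), "DNA"), "")[[1]]
  ## site index facing miRNA position p is L - p + 1
  k_gu <- if (abs(w %% 1 - 0.5) < 1e-9) 1L else 0L
  n_full <- as.integer(floor(w))
  cand <- seq(13L, L, by = 2L)
  gu_ok <- cand[mv[cand] %in% c("G", "U")]
  if (k_gu > length(gu_ok)) stop("infeasible mismatch placement: no wobble-capable position")
  gu_pos <- utils::head(gu_ok, k_gu)
  full_cand <- setdiff(cand, gu_pos)
  if (n_full > length(full_cand)) stop("infeasible mismatch placement: not enough positions")
  full_pos <- utils::head(full_cand, n_full)
  for (p in gu_pos) {
    site[L - p + 1L] <- if (mv[p] == "G") "T" else "G"
  }
  mm_base <- c(A = "C", C = "A", G = "A", U = "C")
  for (p in full_pos) site[L - p + 1L] <- mm_base[[mv[p]]]
  site_str <- paste(site, collapse = "")
  hit <- score_duplex(paste(mv, collapse = ""), site_str)
  stopifnot(abs(hit$total_weighted - w) < 1e-9, hit$rules_pass)
  out <- paste0(substr(gene_seq, 1, position - 1L), site_str,
                substr(gene_seq, position + L, nchar(gene_seq)))
  attr(out, "site") <- site_str
  out
}

#' Generate the complete synthetic study
#'
#' @param config a [sim_config()].
#' @param out_dir when non-NULL, every input file of the pipeline is
#'   written there (FASTA, GFF3, BED, gzipped FASTQ, TSV); otherwise the
#'   bundle is kept in memory only.
#' @param keep_reads keep the per-library read data frames in the bundle
#'   (needed for in-memory pipeline runs).
#' @return list with `bundle` (pipeline inputs), `truth` (planted ground
#'   truth) and `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL, keep_reads = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  params <- mireap_params()
  par <- energy_parameters()
  local_seed(config$seed, {
    stages <- config$stages
    libs <- as.vector(t(outer(stages, seq_len(config$replicates_per_stage),
                              paste0)))
    stage_of <- stats::setNames(rep(stages,
                                    each = config$replicates_per_stage),
                                libs)

    ncrna <- gen_ncrna()
    catalogue <- gen_catalogue(config, ncrna, params, par)
    novel <- gen_novel(config, ncrna, catalogue, params, par)
    genes <- gen_genes(config)

    ## genome assembly; redraw hairpins whose mature is not unique in or
    ## not recoverable from the assembled genome
    bad <- FALSE
    for (attempt in 1:6) {
      asm <- assemble_genome(config, genes, novel)
      mats <- vapply(novel, `[[`, character(1), "mature")
      gh <- genome_hits(mats, asm$genome)
      tt <- data.frame(seq = mats, x = 1L)
      colnames(tt)[2] <- libs[1]
      pn <- predict_novel(tt, asm$genome, params, par)
      bad <- vapply(seq_along(novel), function(i) {
        sum(gh$seq == mats[i]) != 1L ||
          !any(pn$pass & pn$tag == mats[i])
      }, logical(1))
      if (any(bad) && isTRUE(getOption("mirwood.debug"))) {
        message("redrawing hairpins: ", paste(which(bad), collapse = ", "))
      }
      if (!any(bad)) break
      for (i in which(bad)) {
        novel[[i]] <- gen_novel(
          sim_config_replace(config, n_novel_hairpins = 1L),
          ncrna, catalogue, params, par)[[1]]
      }
    }
    if (any(bad)) stop("failed to plant recoverable hairpins")
    gff <- gff_from_coords(asm$coords)
    repeats <- do.call(rbind, lapply(names(asm$coords), function(id) {
      b <- asm$coords[[id]]
      if (b$type != "repeat") return(NULL)
      data.frame(seqid = "chr1", start = b$start, end = b$end, name = id)
    }))

    ## planted DE miRNAs: low-abundance half, alternating direction, one
    ## "effect" stage each, cycled over stages
    features <- c(catalogue$mature$dna,
                  vapply(novel, `[[`, character(1), "mature"))
    star_feats <- vapply(novel, `[[`, character(1), "star")
    nf <- length(features)
    alpha_raw <- stats::rlnorm(nf, 0, 1)
    alpha <- 0.75 * alpha_raw / sum(alpha_raw) + 0.25 / nf
    ord_low <- order(alpha)[seq_len(ceiling(nf / 2))]
    n_de <- min(config$n_de_mirnas, length(ord_low))
    de_idx <- sort(sample(ord_low, n_de))
    mult <- matrix(1, nrow = nf, ncol = length(stages),
                   dimnames = list(features, stages))
    de_stage <- stages[(seq_len(n_de) - 1L) %% length(stages) + 1L]
    de_dirn <- ifelse(seq_len(n_de) %% 2 == 1, 1, -1)
    for (k in seq_len(n_de)) {
      mult[de_idx[k], de_stage[k]] <- 2^(de_dirn[k] * config$effect_log2fc)
    }

    ## planted targets and negative pairs
    mirna_rna <- as_rna(features)
    gene_pool <- seq_along(genes)
    target_rows <- list()
    ## never plant an exact-complement site: it would make the mature map
    ## antisense to the exon and the annotation cascade would claim it
    w_cycle <- c(0.5, 1, 1.5)
    used_genes <- integer(0)
    for (k in seq_len(n_de)) {
      mi <- de_idx[k]
      for (t in seq_len(config$targets_per_mirna)) {
        gcand <- setdiff(gene_pool, used_genes)
        if (!length(gcand)) break
        gi <- sample(gcand, 1)
        used_genes <- c(used_genes, gi)
        g <- genes[[gi]]
        L <- nchar(features[mi])
        lo <- g$e1 + 10L
        hi <- nchar(g$transcript) - L - 5L
        if (hi <= lo) next
        posn <- sample(lo:hi, 1)
        ## plant at the requested weighted-mismatch level, falling back
        ## to lighter levels until the site also clears the duplex
        ## energy-ratio rule (rule 6), so every planted site is
        ## recoverable by the scanner by construction
        perfect <- duplex_mfe(mirna_rna[mi],
                              revcomp(mirna_rna[mi], "RNA"), par)$mfe
        planted <- NULL
        for (wmm in unique(c(w_cycle[(length(target_rows) %% 3) + 1],
                             1, 0.5))) {
          cand <- tryCatch(
            plant_target_site(mirna_rna[mi], g$transcript, wmm, posn),
            error = function(e) NULL)
          if (is.null(cand)) next
          site_mfe <- duplex_mfe(mirna_rna[mi], attr(cand, "site"),
                                 par)$mfe
          if (perfect < 0 && abs(site_mfe) / abs(perfect) >= 0.74) {
            planted <- cand
            break
          }
        }
        if (is.null(planted)) next
        genes[[gi]]$transcript <- as.character(planted)
        asm$genome <- patch_gene_site(asm$genome, asm$coords, g, posn,
                                      attr(planted, "site"))
        coupled <- stats::runif(1) < config$negcorr_fraction
        target_rows[[length(target_rows) + 1L]] <- data.frame(
          mirna_dna = features[mi], gene = g$id, position = posn,
          weighted_mismatches = wmm, coupled = coupled, de_k = k,
          row.names = NULL)
      }
    }
    targets <- if (length(target_rows)) do.call(rbind, target_rows)
               else data.frame()

    ## gene expression model
    ng <- length(genes)
    beta_raw <- stats::rlnorm(ng, 0, 1)
    beta <- 0.75 * beta_raw / sum(beta_raw) + 0.25 / ng
    gmult <- matrix(1, nrow = ng, ncol = length(stages),
                    dimnames = list(vapply(genes, `[[`, character(1), "id"),
                                    stages))
    if (nrow(targets)) {
      for (r in seq_len(nrow(targets))) {
        if (!targets$coupled[r]) next
        k <- targets$de_k[r]
        gmult[targets$gene[r], de_stage[k]] <-
          2^(-de_dirn[k] * config$effect_log2fc)
      }
    }
    free_genes <- setdiff(seq_len(ng), used_genes)
    extra <- sample(free_genes, min(config$n_extra_degs,
                                    length(free_genes)))
    for (j in seq_along(extra)) {
      st <- stages[(j - 1L) %% length(stages) + 1L]
      gmult[extra[j], st] <- 2^(ifelse(j %% 2 == 1, 1, -1) *
                                  config$effect_log2fc)
    }

    ## miRNA + star counts
    mir_counts <- gen_mirna_counts(config, features, alpha, mult, libs,
                                   stage_of)
    star_counts <- matrix(stats::rpois(length(star_feats) * length(libs),
                                       config$star_fraction *
                                         mean(mir_counts)),
                          nrow = length(star_feats),
                          dimnames = list(star_feats, libs))

    ## gene counts
    gene_ids <- rownames(gmult)
    gene_counts <- matrix(0L, nrow = ng, ncol = length(libs),
                          dimnames = list(gene_ids, libs))
    for (l in libs) {
      wg <- beta * gmult[, stage_of[[l]]]
      mu <- config$mrna_depth * wg / sum(beta)
      gene_counts[, l] <- stats::rnbinom(ng, mu = mu,
                                         size = 1 / config$nb_dispersion)
    }
    transcripts <- stats::setNames(
      vapply(genes, `[[`, character(1), "transcript"), gene_ids)
    gene_lengths <- nchar(transcripts)

    ## annotation map
    terms <- sprintf("GO:%07d", seq_len(36))
    ns <- rep(c("BP", "MF", "CC"), length.out = 36)
    ann <- do.call(rbind, lapply(seq_len(ng), function(i) {
      ti <- sample(36, sample(1:4, 1))
      data.frame(gene_id = gene_ids[i], term_id = terms[ti],
                 term_name = paste0("term_", sub("GO:0+", "", terms[ti])),
                 namespace = ns[ti], row.names = NULL)
    }))

    ## read libraries
    reads <- list()
    qc_planted <- list()
    for (l in libs) {
      rl <- gen_library_reads(config, l, mir_counts[, l], star_counts[, l],
                              ncrna, asm, gff, repeats, genes)
      reads[[l]] <- rl$reads
      qc_planted[[l]] <- rl$planted
    }

    ## ground truth
    hairpin_truth <- do.call(rbind, lapply(seq_along(novel), function(i) {
      id <- paste0("hp", i)
      b <- asm$coords[[id]]
      data.frame(id = id, mature_dna = novel[[i]]$mature,
                 arm = novel[[i]]$arm, star_dna = novel[[i]]$star,
                 precursor_dna = novel[[i]]$block,
                 seqid = "chr1", start = b$start, end = b$end,
                 row.names = NULL)
    }))
    cmp_list <- stage_comparisons(stages)
    de_truth <- do.call(rbind, lapply(seq_len(n_de), function(k) {
      i <- de_idx[k]
      do.call(rbind, lapply(cmp_list, function(cmp) {
        lfc <- log2(mult[i, cmp[2]] / mult[i, cmp[1]])
        data.frame(mature_dna = features[i],
                   comparison = paste0(cmp[2], "/", cmp[1]),
                   true_log2fc = lfc, effect_stage = de_stage[k],
                   row.names = NULL)
      }))
    }))
    neg_pairs <- NULL
    if (nrow(targets)) {
      neg_pairs <- do.call(rbind, lapply(which(targets$coupled),
                                         function(r) {
        k <- targets$de_k[r]
        i <- de_idx[k]
        rows <- lapply(cmp_list, function(cmp) {
          lfc <- log2(mult[i, cmp[2]] / mult[i, cmp[1]])
          if (abs(lfc) < 1) return(NULL)
          data.frame(mirna_dna = features[i], gene = targets$gene[r],
                     comparison = paste0(cmp[2], "/", cmp[1]),
                     row.names = NULL)
        })
        do.call(rbind, rows)
      }))
    }
    truth <- list(hairpins = hairpin_truth, de_mirnas = de_truth,
                  targets = targets, negative_pairs = neg_pairs,
                  mirna_counts = mir_counts, star_counts = star_counts,
                  mix = config$contaminant_mix, stage_of = stage_of,
                  qc_planted = qc_planted)

    bundle <- list(
      genome = asm$genome, gff = gff, repeats = repeats, ncrna = ncrna,
      catalogue = catalogue, transcripts = transcripts,
      gene_lengths = gene_lengths, gene_counts = gene_counts,
      annotation = ann, libraries = libs, stage_of = stage_of,
      adapter_3p = config$adapter_3p, adapter_5p = config$adapter_5p,
      reads = if (keep_reads) reads else NULL, files = NULL)

    if (!is.null(out_dir)) {
      bundle$files <- write_bundle(bundle, reads, out_dir)
    }
    list(bundle = bundle, truth = truth, config = config)
  })
}

## write a planted site (placed in exon 2 of the transcript) through to
## the assembled genome, respecting strand
patch_gene_site <- function(genome, coords, gene, posn, site) {
  b <- coords[[gene$id]]
  L <- nchar(site)
  if (gene$strand == "+") {
    g1 <- b$start + gene$intron_len + posn - 1L
    sub <- site
  } else {
    p2 <- posn + L - 1L
    g1 <- b$end - (p2 + gene$intron_len) + 1L
    sub <- revcomp(site)
  }
  chr <- genome[[1]]
  substr(chr, g1, g1 + L - 1L) <- sub
  genome[[1]] <- chr
  genome
}

## modify selected fields of a config without re-validating the rest
sim_config_replace <- function(config, ...) {
  upd <- list(...)
  for (nm in names(upd)) config[[nm]] <- upd[[nm]]
  config
}

## one library's reads: planted class counts, adapters appended, planted
## QC artifacts (5'-adapter contamination, adapter dimers, low-quality
## bases, N bases)
gen_library_reads <- function(config, lib, mir_cnt, star_cnt, ncrna, asm,
                              gff, repeats, genes) {
  mix <- config$contaminant_mix
  depth <- config$library_depth
  inserts <- c(rep(names(mir_cnt), mir_cnt), rep(names(star_cnt), star_cnt))

  n_cl <- function(cl) as.integer(round(depth * mix[[cl]]))
  for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    inserts <- c(inserts, draw_fragments(ncrna[[cl]], n_cl(cl)))
  }
  ## repeat fragments (either strand)
  nrep <- n_cl("repeat")
  if (nrep > 0 && !is.null(repeats)) {
    rep_seqs <- substring(asm$genome[["chr1"]], repeats$start, repeats$end)
    frag <- draw_fragments(rep_seqs, nrep)
    flip <- stats::runif(nrep) < 0.5
    frag[flip] <- revcomp(frag[flip])
    inserts <- c(inserts, frag)
  }
  ## degradation fragments from exons and introns, both orientations
  ndeg <- n_cl("degradation")
  if (ndeg > 0) {
    ex <- gff[gff$type == "exon", , drop = FALSE]
    gn <- gff[gff$type == "gene", , drop = FALSE]
    use_exon <- stats::runif(ndeg) < 0.7
    out <- character(ndeg)
    ex_pick <- sample(nrow(ex), ndeg, replace = TRUE)
    gn_pick <- sample(nrow(gn), ndeg, replace = TRUE)
    src_start <- ifelse(use_exon, ex$start[ex_pick], gn$start[gn_pick])
    src_end <- ifelse(use_exon, ex$end[ex_pick], gn$end[gn_pick])
    L <- sample(18:28, ndeg, replace = TRUE)
    L <- pmin(L, src_end - src_start + 1L)
    st <- src_start + floor(stats::runif(ndeg) * (src_end - src_start -
                                                    L + 2L))
    frag <- substring(asm$genome[["chr1"]], st, st + L - 1L)
    sense <- stats::runif(ndeg) < 0.65
    g_strand <- ifelse(use_exon,
                       gn$strand[match(ex$Parent[ex_pick], gn$ID)],
                       gn$strand[gn_pick])
    read_strand <- ifelse(sense, g_strand,
                          ifelse(g_strand == "+", "-", "+"))
    flip <- read_strand == "-"
    frag[flip] <- revcomp(frag[flip])
    inserts <- c(inserts, frag)
  }
  npa <- n_cl("polyA")
  if (npa > 0) {
    inserts <- c(inserts, strrep("A", sample(18:24, npa, replace = TRUE)))
  }
  nsh <- n_cl("short")
  if (nsh > 0) {
    lens <- sample(12:17, nsh, replace = TRUE)
    inserts <- c(inserts, vapply(lens, random_dna, character(1)))
  }
  inserts <- inserts[sample(length(inserts))]
  n <- length(inserts)
  seqs <- paste0(inserts, config$adapter_3p)

  ## planted QC artifacts
  n5 <- round(0.004 * n)
  nno <- round(0.0025 * n)
  nlq <- round(0.002 * n)
  nN <- round(0.001 * n)
  art <- sample(n, n5 + nno + nlq + nN)
  i5 <- art[seq_len(n5)]
  ino <- art[n5 + seq_len(nno)]
  ilq <- art[n5 + nno + seq_len(nlq)]
  iN <- art[n5 + nno + nlq + seq_len(nN)]
  seqs[i5] <- paste0(config$adapter_5p, inserts[i5], config$adapter_3p)
  seqs[ino] <- paste0(config$adapter_5p, config$adapter_3p)
  quals <- strrep("I", nchar(seqs))
  if (length(ilq)) {
    len <- nchar(seqs[ilq])
    p1 <- 1L + floor(stats::runif(length(ilq)) * len)
    p2 <- p1 %% len + 1L
    q <- quals[ilq]
    substr(q, p1, p1) <- "4"
    substr(q, p2, p2) <- "4"
    quals[ilq] <- q
  }
  if (length(iN)) {
    s <- seqs[iN]
    pN <- 1L + floor(stats::runif(length(iN)) * nchar(s))
    substr(s, pN, pN) <- "N"
    seqs[iN] <- s
  }
  list(reads = data.frame(id = paste0(lib, "_", seq_len(n)), seq = seqs,
                          qual = quals, row.names = NULL),
       planted = list(n = n, n_5p = n5, n_no_insert = nno, n_lowq = nlq,
                      n_N = nN))
}

write_bundle <- function(bundle, reads, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  files <- list(genome = fp("genome.fa"), gff = fp("genes.gff3"),
                repeats = fp("repeats.bed"), mature = fp("mature.fa"),
                hairpin = fp("hairpin.fa"),
                mrna_counts = fp("mrna_counts.tsv"),
                annotation = fp("annotation.tsv"))
  write_fasta(bundle$genome, files$genome)
  write_gff3(bundle$gff, files$gff)
  write_bed(bundle$repeats, files$repeats)
  for (cl in names(bundle$ncrna)) {
    files[[cl]] <- fp(paste0(cl, ".fa"))
    write_fasta(bundle$ncrna[[cl]], files[[cl]])
  }
  write_fasta(stats::setNames(bundle$catalogue$mature$seq,
                              bundle$catalogue$mature$name), files$mature)
  write_fasta(bundle$catalogue$hairpin, files$hairpin)
  write_counts(bundle$gene_counts, files$mrna_counts, id_col = "gene_id")
  utils::write.table(bundle$annotation, files$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$fastq <- character(0)
  for (l in names(reads)) {
    f <- fp(paste0(l, ".fastq.gz"))
    write_fastq(reads[[l]], f)
    files$fastq[l] <- f
  }
  files
}

#' Count-level miRNA simulator for calibration and power studies
#'
#' Draws NB counts for two groups of replicates with an optional planted
#' fold change on a subset of features, without the read-level machinery.
#'
#' @param n_features number of features.
#' @param n_per_group replicates per group.
#' @param mean_count median feature abundance (counts per replicate).
#' @param dispersion NB dispersion.
#' @param effect_log2fc planted |log2FC| applied to `de_fraction` of
#'   features (alternating sign).
#' @param de_fraction fraction of features with the planted effect.
#' @param seed optional seed.
#' @return list with `counts` (features x 2*n_per_group), `groups`,
#'   `de_idx` and `true_log2fc`.
#' @export
simulate_mirna_counts <- function(n_features, n_per_group = 3,
                                  mean_count = 200, dispersion = 0.05,
                                  effect_log2fc = 0, de_fraction = 0,
                                  seed = NULL) {
  run <- function() {
    mu <- stats::rlnorm(n_features, log(mean_count), 0.7)
    n_de <- round(de_fraction * n_features)
    de_idx <- if (n_de > 0) sort(sample(n_features, n_de)) else integer(0)
    lfc <- numeric(n_features)
    if (n_de > 0) {
      lfc[de_idx] <- effect_log2fc * ifelse(seq_len(n_de) %% 2 == 1, 1, -1)
    }
    size <- if (dispersion > 0) 1 / dispersion else Inf
    draw <- function(m) {
      if (is.finite(size)) stats::rnbinom(length(m), mu = m, size = size)
      else stats::rpois(length(m), m)
    }
    counts <- cbind(
      matrix(draw(rep(mu, n_per_group)), ncol = n_per_group),
      matrix(draw(rep(mu * 2^lfc, n_per_group)), ncol = n_per_group))
    rownames(counts) <- paste0("f", seq_len(n_features))
    colnames(counts) <- c(paste0("A", seq_len(n_per_group)),
                          paste0("B", seq_len(n_per_group)))
    list(counts = counts,
         groups = rep(c("A", "B"), each = n_per_group),
         de_idx = de_idx, true_log2fc = lfc)
  }
  if (is.null(seed)) run() else local_seed(seed, run())
}
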