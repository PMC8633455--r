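## End-to-end orchestration: QC -> tag collapse -> annotation cascade ->
## known/conserved assignment -> novel prediction -> TPM/FPKM + DE ->
## target scan -> pair correlation -> enrichment, with a manifest of
## per-stage counts and every threshold echoed.

#' Pipeline thresholds and toggles
#'
#' @param lfc_min |log2FC| threshold shared by miRNAs and genes.
#' @param mirna_p_max raw p threshold for DE miRNAs.
#' @param gene_fdr_max BH FDR threshold for DE genes.
#' @param r_neg negative-correlation boundary (strict, open interval at
#'   -1).
#' @param cor_p_max correlation p threshold.
#' @param enrich_fdr_max enrichment FDR threshold.
#' @param rules target-prediction rule set ([target_rules()]).
#' @param mireap structural criteria ([mireap_params()]).
#' @param lfc_pseudo pseudocount for fold changes (TPM/FPKM units).
#' @param min_len,max_low_qual sRNA QC settings.
#' @export
pipeline_thresholds <- function(lfc_min = 1, mirna_p_max = 0.05,
                                gene_fdr_max = 0.05, r_neg = -0.8,
                                cor_p_max = 0.05, enrich_fdr_max = 0.05,
                                rules = target_rules(),
                                mireap = mireap_params(),
                                lfc_pseudo = 0.5, min_len = 18L,
                                max_low_qual = 1L) {
  as.list(environment())
}

#' Load a written bundle back from disk
#'
#' @param dir directory produced by [simulate_dataset()] with `out_dir`.
#' @param stages stage labels used to map library files to stages.
#' @export
load_bundle <- function(dir, stages = c("PS", "TS", "SS")) {
  fp <- function(x) file.path(dir, x)
  fastqs <- sort(list.files(dir, pattern = "\\.fastq\\.gz$",
                            full.names = TRUE))
  libs <- sub("\\.fastq\\.gz$", "", basename(fastqs))
  stage_of <- stats::setNames(sub("[0-9]+$", "", libs), libs)
  libs <- libs[order(match(stage_of[libs], stages), libs)]
  mat <- read_fasta(fp("mature.fa"))
  catalogue <- list(
    mature = data.frame(name = names(mat), seq = unname(mat),
                        precursor = sub("-(5p|3p)$", "",
                                        sub("miR", "MIR", names(mat))),
                        focal = grepl("^ptc-", names(mat)),
                        row.names = NULL),
    hairpin = read_fasta(fp("hairpin.fa")))
  gff <- read_gff3(fp("genes.gff3"))
  genome <- read_fasta(fp("genome.fa"))
  list(genome = genome, gff = gff,
       repeats = read_bed(fp("repeats.bed")),
       ncrna = list(rRNA = read_fasta(fp("rRNA.fa")),
                    tRNA = read_fasta(fp("tRNA.fa")),
                    snRNA = read_fasta(fp("snRNA.fa")),
                    snoRNA = read_fasta(fp("snoRNA.fa"))),
       catalogue = catalogue,
       transcripts = splice_transcripts(genome, gff),
       gene_counts = read_counts(fp("mrna_counts.tsv")),
       annotation = utils::read.delim(fp("annotation.tsv")),
       libraries = libs, stage_of = stage_of[libs],
       adapter_3p = NULL, adapter_5p = NULL,
       reads = NULL,
       files = c(list(fastq = stats::setNames(fastqs, sub(
         "\\.fastq\\.gz$", "", basename(fastqs)))), list()))
}

#' Spliced transcript sequences from a genome and gene models
#' @param genome named character vector; `gff` gene table.
#' @export
splice_transcripts <- function(genome, gff) {
  genes <- gff[gff$type == "gene", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  out <- character(nrow(genes))
  names(out) <- genes$ID
  for (i in seq_len(nrow(genes))) {
    ex <- exons[exons$Parent == genes$ID[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    seqs <- substring(genome[[genes$seqid[i]]], ex$start, ex$end)
    tx <- paste(seqs, collapse = "")
    if (genes$strand[i] == "-") tx <- revcomp(tx)
    out[genes$ID[i]] <- tx
  }
  out
}

#' Run the full pipeline on a bundle
#'
#' @param bundle in-memory bundle from [simulate_dataset()] or
#'   [load_bundle()].
#' @param thresholds [pipeline_thresholds()].
#' @param adapter_3p,adapter_5p adapters (default: taken from the bundle).
#' @return list with all stage outputs and a `manifest` of counts.
#' @export
run_pipeline <- function(bundle, thresholds = pipeline_thresholds(),
                         adapter_3p = bundle$adapter_3p,
                         adapter_5p = bundle$adapter_5p) {
  stopifnot(!is.null(adapter_3p), !is.null(adapter_5p))
  libs <- bundle$libraries
  stage_of <- bundle$stage_of

  ## 1. QC
  clean <- list()
  qc <- list()
  for (l in libs) {
    raw <- if (!is.null(bundle$reads)) bundle$reads[[l]]
           else read_fastq(bundle$files$fastq[[l]])
    res <- clean_srna_reads(raw, adapter_3p, adapter_5p,
                            min_len = thresholds$min_len,
                            max_low_qual = thresholds$max_low_qual)
    clean[[l]] <- res$reads
    qc[[l]] <- res$report
  }
  totals <- vapply(qc, function(r) as.numeric(r$clean), numeric(1))

  ## 2. collapse and annotate
  tags <- collapse_tags(clean)
  refs <- list(ncrna = bundle$ncrna, genome = bundle$genome,
               repeats = bundle$repeats, gff = bundle$gff,
               catalogue = bundle$catalogue)
  cls <- classify_tags(tags, refs)
  distr <- category_distribution(tags, cls)
  lens <- length_distribution(tags)

  ## 3. known and novel miRNAs
  mir_tags <- tags[cls$category == "miRNA", , drop = FALSE]
  known <- assign_known(mir_tags, bundle$catalogue)
  un_tags <- tags[cls$category == "unannotated", , drop = FALSE]
  cands <- predict_novel(un_tags, bundle$genome, thresholds$mireap)
  novel <- dedupe_candidates(cands, un_tags)

  ## 4. miRNA expression: merge known + novel records; counts of records
  ## sharing a name are summed
  info <- rbind(known$info[, c("name", "status", "arm", "mature",
                               "tag_seq")],
                novel$info[, c("name", "status", "arm", "mature",
                               "tag_seq")])
  cnt <- rbind(known$counts, novel$counts)
  mir_counts <- rowsum(cnt, group = info$name)
  mode(mir_counts) <- "integer"
  tpm <- tpm_normalize(mir_counts, totals)

  ## 5. DE per comparison
  stages <- unique(stage_of[libs])
  cmp_list <- stage_comparisons(stages)
  de_mirnas <- list()
  degs <- list()
  glen_all <- bundle$gene_lengths %||% nchar(bundle$transcripts)
  glen <- as.numeric(glen_all[rownames(bundle$gene_counts)])
  fpkm <- fpkm_normalize(bundle$gene_counts, glen)
  for (cmp in cmp_list) {
    key <- paste0(cmp[2], "/", cmp[1])
    de_mirnas[[key]] <- call_de_mirnas(
      mir_counts, totals, stage_of[libs], cmp,
      lfc_min = thresholds$lfc_min, p_max = thresholds$mirna_p_max,
      lfc_pseudo = thresholds$lfc_pseudo)
    degs[[key]] <- call_degs(
      bundle$gene_counts, glen, stage_of[libs], cmp,
      lfc_min = thresholds$lfc_min, fdr_max = thresholds$gene_fdr_max,
      lfc_pseudo = thresholds$lfc_pseudo)
  }

  ## 6. target scan for all DE miRNAs (union over comparisons)
  de_names <- unique(unlist(lapply(de_mirnas,
                                   function(d) d$feature[d$called])))
  name2seq <- stats::setNames(info$mature, info$name)
  hits <- if (length(de_names)) {
    scan_transcriptome(name2seq[de_names], bundle$transcripts,
                       thresholds$rules)
  } else {
    scan_transcriptome(character(0), bundle$transcripts, thresholds$rules)
  }

  ## 7. integration per comparison
  pairs <- list()
  networks <- list()
  for (key in names(de_mirnas)) {
    cmp <- strsplit(key, "/", fixed = TRUE)[[1]][2:1]
    p0 <- build_pairs(de_mirnas[[key]], hits, degs[[key]])
    lib6 <- libs[stage_of[libs] %in% cmp]
    cl <- classify_pairs(p0, tpm, fpkm, lib6, r_neg = thresholds$r_neg,
                         p_max = thresholds$cor_p_max)
    pairs[[key]] <- cl
    networks[[key]] <- dedupe_network(cl$records)
  }

  ## 8. enrichment of the CTGs of each comparison
  enrich <- list()
  population <- rownames(bundle$gene_counts)
  for (key in names(pairs)) {
    ctgs <- unique(pairs[[key]]$records$ctg)
    enrich[[key]] <- if (length(ctgs)) {
      enrich_terms(ctgs, population, bundle$annotation,
                   fdr_max = thresholds$enrich_fdr_max)
    } else {
      NULL
    }
  }

  manifest <- build_manifest(thresholds, qc, tags, distr, known, novel,
                             de_mirnas, degs, hits, pairs, networks)
  list(qc = qc, tags = tags, classification = cls, distribution = distr,
       length_distribution = lens, known = known, candidates = cands,
       novel = novel, mirna_counts = mir_counts, tpm = tpm, fpkm = fpkm,
       totals = totals, de_mirnas = de_mirnas, degs = degs, hits = hits,
       pairs = pairs, networks = networks, enrichment = enrich,
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_manifest <- function(thresholds, qc, tags, distr, known, novel,
                           de_mirnas, degs, hits, pairs, networks) {
  counts <- list(
    raw_reads = sum(vapply(qc, function(r) as.numeric(r$total_raw),
                           numeric(1))),
    clean_reads = sum(vapply(qc, function(r) as.numeric(r$clean),
                             numeric(1))),
    unique_tags = nrow(tags),
    known_records = nrow(known$info),
    existing = sum(known$info$status == "existing"),
    conserved = sum(known$info$status == "conserved"),
    novel = nrow(novel$info),
    de_mirnas = vapply(de_mirnas, function(d) sum(d$called), numeric(1)),
    degs = vapply(degs, function(d) sum(d$called), numeric(1)),
    target_hits = nrow(hits),
    pairs = vapply(pairs, function(p) p$summary$n_pairs, numeric(1)),
    negative_pairs = vapply(pairs, function(p) p$summary$n_negative,
                            numeric(1)),
    positive_pairs = vapply(pairs, function(p) p$summary$n_positive,
                            numeric(1)),
    none_pairs = vapply(pairs, function(p) p$summary$n_none, numeric(1)),
    unique_neg_mirnas = vapply(networks, function(n) n$n_mirnas,
                               numeric(1)),
    unique_neg_ctgs = vapply(networks, function(n) n$n_ctgs, numeric(1))
  )
  th <- thresholds
  th$rules <- NULL
  th$mireap <- NULL
  list(package_version = as.character(utils::packageVersion("mirwood")),
       thresholds = c(th, thresholds$rules, thresholds$mireap),
       counts = counts)
}

#' Score a pipeline run against planted ground truth
#'
#' @param run result of [run_pipeline()].
#' @param truth ground truth from [simulate_dataset()].
#' @return data.frame of per-stage metrics (sensitivity / precision /
#'   counts); DE metrics are aggregated over comparisons against the
#'   planted |log2FC| >= 1 set.
#' @export
evaluate_against_truth <- function(run, truth) {
  metrics <- list()
  add <- function(stage, metric, value, n = NA) {
    metrics[[length(metrics) + 1L]] <<- data.frame(
      stage = stage, metric = metric, value = value, n = n,
      row.names = NULL)
  }

  ## hairpin recovery
  planted <- truth$hairpins$mature_dna
  found <- run$novel$info$tag_seq
  add("discovery", "hairpin_recall",
      if (length(planted)) mean(planted %in% found) else NA,
      length(planted))
  extra <- setdiff(found, planted)
  add("discovery", "hairpin_extra_candidates", length(extra))

  ## DE miRNAs: planted features keyed by mature DNA sequence
  seq_of <- stats::setNames(run$known$info$tag_seq, run$known$info$name)
  seq_of <- c(seq_of, stats::setNames(run$novel$info$tag_seq,
                                      run$novel$info$name))
  tp <- 0; fn <- 0; fp <- 0
  for (key in names(run$de_mirnas)) {
    d <- run$de_mirnas[[key]]
    called_seq <- unique(stats::na.omit(seq_of[d$feature[d$called]]))
    pl <- truth$de_mirnas
    pl <- pl[pl$comparison == key & abs(pl$true_log2fc) >= 1, ,
             drop = FALSE]
    tp <- tp + sum(pl$mature_dna %in% called_seq)
    fn <- fn + sum(!pl$mature_dna %in% called_seq)
    fp <- fp + sum(!called_seq %in% pl$mature_dna)
  }
  add("de_mirna", "sensitivity",
      if (tp + fn > 0) tp / (tp + fn) else NA, tp + fn)
  add("de_mirna", "fdp", if (tp + fp > 0) fp / (tp + fp) else NA, tp + fp)

  ## negative pairs
  if (!is.null(truth$negative_pairs) && nrow(truth$negative_pairs)) {
    tpn <- 0; fnn <- 0
    for (r in seq_len(nrow(truth$negative_pairs))) {
      key <- truth$negative_pairs$comparison[r]
      rec <- run$pairs[[key]]$records
      neg <- rec[rec$cls == "negative", , drop = FALSE]
      hit <- FALSE
      if (nrow(neg)) {
        hit <- any(seq_of[neg$mirna] == truth$negative_pairs$mirna_dna[r] &
                     neg$ctg == truth$negative_pairs$gene[r], na.rm = TRUE)
      }
      if (hit) tpn <- tpn + 1 else fnn <- fnn + 1
    }
    add("integration", "negative_pair_sensitivity", tpn / (tpn + fnn),
        tpn + fnn)
  } else {
    add("integration", "negative_pair_sensitivity", NA, 0)
  }
  do.call(rbind, metrics)
}
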