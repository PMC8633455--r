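# A miniature hand-built reference bundle: one chromosome carrying one
# two-exon gene on each strand, one repeat interval, plus structural-RNA
# sets and a two-entry catalogue.
mini_refs <- function() {
  set.seed(407)
  rr <- rand_seq(300, c("A", "C", "G", "T"))
  tr <- rand_seq(150, c("A", "C", "G", "T"))
  exon1p <- rand_seq(120, c("A", "C", "G", "T"))
  intronp <- rand_seq(90, c("A", "C", "G", "T"))
  exon2p <- rand_seq(120, c("A", "C", "G", "T"))
  gene_m <- rand_seq(200, c("A", "C", "G", "T"))
  rep_seq <- rand_seq(150, c("A", "C", "G", "T"))
  filler <- function(n) rand_seq(n, c("A", "C", "G", "T"))
  genome <- paste0(filler(50), exon1p, intronp, exon2p, filler(40),
                   gene_m, filler(40), rep_seq, filler(50))
  gp_start <- 51
  gm_start <- 51 + 330 + 40
  rep_start <- gm_start + 200 + 40
  gff <- data.frame(
    seqid = "chr1",
    type = c("gene", "exon", "exon", "gene", "exon"),
    start = c(gp_start, gp_start, gp_start + 210, gm_start, gm_start),
    end = c(gp_start + 329, gp_start + 119, gp_start + 329,
            gm_start + 199, gm_start + 199),
    strand = c("+", "+", "+", "-", "-"),
    ID = c("gplus", "gplus.e1", "gplus.e2", "gminus", "gminus.e1"),
    Parent = c(NA, "gplus", "gplus", NA, "gminus"))
  list(ncrna = list(rRNA = c(rRNA_1 = rr), tRNA = c(tRNA_1 = tr),
                    snRNA = c(snRNA_1 = rand_seq(100, c("A", "C", "G", "T"))),
                    snoRNA = c(snoRNA_1 = rand_seq(100, c("A", "C", "G", "T")))),
       genome = c(chr1 = genome),
       repeats = data.frame(seqid = "chr1", start = rep_start,
                            end = rep_start + 149),
       gff = gff,
       catalogue = list(mature = data.frame(
         name = c("ptc-miR9001", "ath-miR9002"),
         seq = c("UGGACGGAGAACUGAUAAGGGU", "UCGAUAAACCUCUGCAUCCAG"),
         precursor = c("ptc-MIR9001", "ath-MIR9002"),
         focal = c(TRUE, FALSE))),
       pieces = list(rr = rr, exon1p = exon1p, intronp = intronp,
                     exon2p = exon2p, gene_m = gene_m, rep_seq = rep_seq))
}

test_that("collapse merges duplicate sequences and is order-invariant", {
  reads <- list(PS1 = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
                        "ACGTACGTACGTACGTACGTA"),
                PS2 = c("ACGTACGTACGTACGTACGTA", "TTTTGGGGCCCCAAAATTTTG"))
  tt <- collapse_tags(reads)
  expect_equal(nrow(tt), 2)
  expect_equal(tt$PS1[tt$seq == "ACGTACGTACGTACGTACGTA"], 3L)
  expect_equal(tt$PS2[tt$seq == "ACGTACGTACGTACGTACGTA"], 1L)
  expect_equal(sum(tag_counts(tt)), 5)
  shuffled <- lapply(reads, function(x) x[sample(length(x))])
  expect_identical(tt, collapse_tags(shuffled))
})

test_that("the precedence cascade assigns exactly one category per tag", {
  refs <- mini_refs()
  p <- refs$pieces
  tags <- data.frame(seq = c(
    substr(p$rr, 11, 32),                 # rRNA fragment
    substr(p$exon1p, 5, 26),              # exon fragment, sense (+ gene)
    revcomp(substr(p$exon1p, 40, 61)),    # exon fragment, antisense
    substr(p$intronp, 10, 31),            # intron, sense
    revcomp(substr(p$gene_m, 20, 41)),    # minus-strand gene exon, sense
    substr(p$rep_seq, 30, 51),            # repeat
    chartr("U", "T", refs$catalogue$mature$seq[1]),  # catalogue mature
    "GCGCGCGCATATATATGCGCGCA"),           # nothing
    PS1 = 1L)
  cls <- classify_tags(tags, refs)
  expect_equal(as.character(cls$category),
               c("rRNA", "exon_sense", "exon_antisense", "intron_sense",
                 "exon_sense", "repeat", "miRNA", "unannotated"))
})

test_that("an rRNA match wins over an exon match (precedence)", {
  refs <- mini_refs()
  frag <- substr(refs$pieces$exon1p, 5, 26)
  refs$ncrna$rRNA <- c(refs$ncrna$rRNA,
                       rRNA_hybrid = paste0("CCCC", frag, "GGGG"))
  cls <- classify_tags(data.frame(seq = frag, PS1 = 1L), refs)
  expect_equal(as.character(cls$category), "rRNA")
})

test_that("category distribution is abundance-weighted and sums to 100%", {
  refs <- mini_refs()
  p <- refs$pieces
  tags <- data.frame(seq = c(substr(p$rr, 11, 32), substr(p$rr, 12, 33),
                             "GCGCGCGCATATATATGCGCGCA"),
                     PS1 = c(7L, 2L, 1L), PS2 = c(0L, 0L, 4L))
  cls <- classify_tags(tags, refs)
  d <- category_distribution(tags, cls)
  expect_equal(sum(d$percent[d$library == "PS1"]), 100)
  expect_equal(sum(d$percent[d$library == "PS2"]), 100)
  expect_equal(d$count[d$library == "PS1" & d$category == "rRNA"], 9L)
  expect_equal(d$percent[d$library == "PS1" & d$category == "rRNA"], 90)
  expect_equal(sum(d$count[d$library == "PS1"]), sum(tags$PS1))
})

test_that("length distribution is abundance-weighted per library", {
  tags <- data.frame(seq = c(rand_seq(21, c("A", "C")), rand_seq(24, c("A", "C"))),
                     PS1 = c(3L, 1L), PS2 = c(0L, 0L))
  expect_warning(h <- length_distribution(tags), "empty")
  expect_equal(h["21", "PS1"], 0.75)
  expect_equal(h["24", "PS1"], 0.25)
  expect_equal(sum(h[, "PS1"]), 1)
  expect_equal(sum(h[, "PS2"]), 0)
})

test_that("a missing reference class raises a configuration error", {
  refs <- mini_refs()
  refs$ncrna$snoRNA <- NULL
  expect_error(classify_tags(data.frame(seq = "ACGTACGTACGTACGTACGTA",
                                        PS1 = 1L), refs), "snoRNA")
})

test_that("on simulated data the mix proportions are recovered and the
           unannotated pool holds exactly the planted hairpin tags", {
  sim <- small_sim()
  run <- small_run()
  d <- run$distribution
  total_by_cat <- tapply(d$count, d$category, sum)
  frac <- total_by_cat / sum(total_by_cat)
  mix <- sim$truth$mix
  ## reads lost to planted QC artifacts are class-independent, so clean
  ## fractions track the planted mix
  for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    expect_lt(abs(frac[[cl]] - mix[[cl]]), 0.01)
  }
  ## the mirna proportion covers catalogue matures (classified miRNA) and
  ## the planted novel matures and stars (unannotated by design)
  expect_lt(abs(frac[["miRNA"]] + frac[["unannotated"]] - mix[["mirna"]]),
            0.04)
  un <- run$tags$seq[run$classification$category == "unannotated"]
  expect_true(all(sim$truth$hairpins$mature_dna %in% un))
  planted_contams <- names(sim$truth$mix)
  expect_false(any(run$tags$seq[run$classification$category == "rRNA"]
                   %in% sim$truth$hairpins$mature_dna))
})
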