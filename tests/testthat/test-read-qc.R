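A3 <- "AGATCGGAAGAGCACACGTCT"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

mk_read <- function(seq, qual = strrep("I", nchar(seq)), id = "r") {
  data.frame(id = id, seq = seq, qual = qual)
}

test_that("a full-adapter read is kept and trimmed to its insert", {
  ins <- "ACGTACGTACGTACGTACGTA"
  res <- clean_srna_reads(mk_read(paste0(ins, A3)), A3, A5)
  expect_equal(res$reads$seq, ins)
  expect_equal(nchar(res$reads$qual), nchar(ins))
  expect_equal(res$report$clean, 1L)
})

test_that("one low-quality base passes, two fail, any N fails", {
  ins <- paste0("ACGTACGTACGTACGTACGTA", A3)
  q1 <- strrep("I", nchar(ins))
  substr(q1, 3, 3) <- "4"                      # one base at Phred 19
  q2 <- q1
  substr(q2, 7, 7) <- "5"                      # second base at Phred 20
  one <- clean_srna_reads(mk_read(ins, q1), A3, A5)
  two <- clean_srna_reads(mk_read(ins, q2), A3, A5)
  expect_equal(one$report$clean, 1L)
  expect_equal(two$report$removed_low_quality, 1L)
  withN <- sub("ACGT", "ACGN", ins)
  expect_equal(clean_srna_reads(mk_read(withN), A3,
                                A5)$report$removed_low_quality, 1L)
})

test_that("the 18-nt insert boundary is inclusive", {
  r17 <- clean_srna_reads(mk_read(paste0(rand_seq(17, c("C", "G")), A3)),
                          A3, A5)
  r18 <- clean_srna_reads(mk_read(paste0(rand_seq(18, c("C", "G")), A3)),
                          A3, A5)
  expect_equal(r17$report$removed_short, 1L)
  expect_equal(r18$report$clean, 1L)
})

test_that("adapter classes are detected", {
  ins <- "ACGTACGTACGTACGTACGTA"
  d <- detect_adapter(c(paste0(ins, A3),            # 3' only
                        paste0(A5, ins, A3),        # 5' contamination
                        paste0(A5, A3),             # dimer, no insert
                        ins,                        # no adapter at all
                        paste0(strrep("A", 20), A3)),
                      A3, A5)
  expect_equal(d$class,
               c("3p_only", "5p_only", "both_no_insert", "none", "polyA"))
  expect_equal(d$insert[1], ins)
  expect_equal(d$insert[3], "")
})

test_that("seed-and-extend tolerates one mismatch in the adapter tail", {
  ins <- "ACGTACGTACGTACGTACGTA"
  a_mut <- A3
  substr(a_mut, 15, 15) <- "A"   # mismatch beyond the 8-nt seed
  d <- detect_adapter(paste0(ins, a_mut), A3, A5)
  expect_equal(d$class, "3p_only")
  expect_equal(d$insert, ins)
  a_seed_mut <- A3
  substr(a_seed_mut, 5, 5) <- "T"  # mismatch inside the seed: no match
  expect_equal(detect_adapter(paste0(ins, a_seed_mut), A3, A5)$class,
               "none")
})

test_that("malformed records are dropped and counted", {
  bad <- data.frame(id = "m", seq = "ACGTACGT", qual = "III")
  expect_message(res <- clean_srna_reads(bad, A3, A5), "malformed")
  expect_equal(res$report$malformed, 1L)
  expect_equal(res$report$total_raw, 1L)
})

test_that("QC report counts always sum to the raw total (property)", {
  set.seed(405)
  for (rep in 1:5) {
    n <- 300
    ins <- vapply(sample(10:30, n, TRUE), function(L)
      rand_seq(L, c("A", "C", "G", "T")), character(1))
    seqs <- paste0(ins, A3)
    swap <- runif(n)
    seqs[swap < 0.05] <- paste0(A5, ins[swap < 0.05], A3)
    seqs[swap > 0.97] <- ins[swap > 0.97]
    qual <- strrep("I", nchar(seqs))
    lq <- which(swap > 0.9 & swap <= 0.97)
    substr(qual[lq], 1, 2) <- "44"
    reads <- data.frame(id = paste0("r", 1:n), seq = seqs, qual = qual)
    rep1 <- clean_srna_reads(reads, A3, A5)$report
    expect_equal(rep1$malformed + rep1$removed_low_quality +
                   rep1$removed_adapter_artifact + rep1$removed_polyA +
                   rep1$removed_short + rep1$clean, rep1$total_raw)
    ## report totals are order-independent
    perm <- sample(n)
    rep2 <- clean_srna_reads(reads[perm, ], A3, A5)$report
    expect_equal(qc_report_df(rep1), qc_report_df(rep2))
  }
})

test_that("re-filtering already-trimmed inserts removes nothing", {
  set.seed(406)
  ins <- vapply(rep(21, 50), function(L) rand_seq(L, c("A", "C", "G", "T")),
                character(1))
  reads <- data.frame(id = paste0("r", 1:50), seq = paste0(ins, A3),
                      qual = strrep("I", 21 + nchar(A3)))
  first <- clean_srna_reads(reads, A3, A5)
  again <- clean_srna_reads(first$reads, A3, A5, require_adapter = FALSE)
  expect_equal(again$report$clean, first$report$clean)
  expect_equal(again$reads$seq, first$reads$seq)
})

test_that("mRNA pair filters respect the 50-nt, 10% N and 50% quality bounds", {
  mk <- function(seq, qual = strrep("I", nchar(seq))) {
    data.frame(id = "p", seq = seq, qual = qual)
  }
  good <- rand_seq(125, c("A", "C", "G", "T"))
  ## 13 Ns in 125 nt = 10.4% fails; 12 = 9.6% passes
  n13 <- paste0(strrep("N", 13), substr(good, 14, 125))
  n12 <- paste0(strrep("N", 12), substr(good, 13, 125))
  r13 <- clean_mrna_reads(mk(n13), mk(good), A3)
  r12 <- clean_mrna_reads(mk(n12), mk(good), A3)
  expect_equal(r13$report$removed_N, 1L)
  expect_equal(r12$report$clean, 1L)
  ## 49 nt after trimming fails, 50 passes
  r49 <- clean_mrna_reads(mk(paste0(substr(good, 1, 49), A3)), mk(good), A3)
  r50 <- clean_mrna_reads(mk(paste0(substr(good, 1, 50), A3)), mk(good), A3)
  expect_equal(r49$report$removed_short, 1L)
  expect_equal(r50$report$clean, 1L)
  ## 51 of 100 bases at Phred 20 fails; 50 passes
  s100 <- substr(good, 1, 100)
  q51 <- paste0(strrep("5", 51), strrep("I", 49))
  q50 <- paste0(strrep("5", 50), strrep("I", 50))
  expect_equal(clean_mrna_reads(mk(s100, q51), mk(s100), A3)
               $report$removed_low_quality, 1L)
  expect_equal(clean_mrna_reads(mk(s100, q50), mk(s100), A3)$report$clean,
               1L)
  ## a pair is dropped when either mate fails
  expect_equal(clean_mrna_reads(mk(good), mk(n13), A3)$report$removed_N, 1L)
})

test_that("orphan mates are logged as malformed", {
  r1 <- data.frame(id = c("a", "b"), seq = rep(rand_seq(80, LETTERS[c(1, 3, 7, 20)]), 2),
                   qual = rep(strrep("I", 80), 2))
  r2 <- r1[1, , drop = FALSE]
  expect_message(res <- clean_mrna_reads(r1, r2, A3), "orphan")
  expect_equal(res$report$malformed, 1L)
})
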