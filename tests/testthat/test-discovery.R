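# helper: a hairpin block with known geometry (mature on the given arm)
mk_hairpin <- function(mature, arm = "5p", gap = 18) {
  star <- paste0(revcomp(substr(mature, 1, nchar(mature) - 2)),
                 strrep("A", 2))
  core <- if (arm == "5p") paste0(mature, strrep("C", gap), star)
          else paste0(star, strrep("C", gap), mature)
  paste0(strrep("A", 20), core, strrep("A", 20))
}

test_that("existing and conserved assignment follows the naming rules", {
  set.seed(408)
  m1 <- "TGGACGGAGAACTGATAAGGGT"  # focal, 5' arm
  m2 <- "TCGATAAACCTCTGCATCCAG"   # other species, 3' arm
  catalogue <- list(
    mature = data.frame(
      name = c("ptc-miR9001", "ath-miR9002a-3p"),
      seq = chartr("T", "U", c(m1, m2)),
      precursor = c("ptc-MIR9001", "ath-MIR9002"),
      focal = c(TRUE, FALSE)),
    hairpin = c("ptc-MIR9001" = chartr("T", "U", mk_hairpin(m1, "5p")),
                "ath-MIR9002" = chartr("T", "U", mk_hairpin(m2, "3p"))))
  tags <- data.frame(seq = c(m1, m2, "ACGTACGTACGTACGTACGTA"),
                     PS1 = c(10L, 5L, 2L), TS1 = c(1L, 0L, 0L))
  res <- assign_known(tags, catalogue)
  expect_equal(nrow(res$info), 2)           # unmatched tag stays out
  ex <- res$info[res$info$status == "existing", ]
  expect_equal(ex$name, "ptc-miR9001-5p")   # arm suffix appended
  expect_equal(ex$arm, "5p")
  co <- res$info[res$info$status == "conserved", ]
  expect_equal(co$name, "miR9002a-y")       # renamed with -y (3' arm)
  expect_equal(co$arm, "y")
  expect_equal(unname(res$counts[res$info$status == "existing", "PS1"]),
               10L)
  expect_error(assign_known(tags, list(mature = NULL)), "catalogue")
})

test_that("a focal-species match beats an other-species match", {
  m <- "TGGACGGAGAACTGATAAGGGT"
  catalogue <- list(
    mature = data.frame(
      name = c("zma-miR9009", "ptc-miR9001"),
      seq = chartr("T", "U", c(m, m)),
      precursor = c("zma-MIR9009", "ptc-MIR9001"),
      focal = c(FALSE, TRUE)),
    hairpin = c("ptc-MIR9001" = chartr("T", "U", mk_hairpin(m, "5p"))))
  res <- assign_known(data.frame(seq = m, PS1 = 1L), catalogue)
  expect_equal(res$info$status, "existing")
  expect_match(res$info$name, "^ptc-")
})

test_that("a planted hairpin locus yields exactly one passing candidate", {
  set.seed(409)
  mature <- "TGCACGTTCGATAGCTAGCTT"
  block <- mk_hairpin(mature, "5p")
  genome <- c(chr1 = paste0(rand_seq(300, c("A", "C", "G", "T")), block,
                            rand_seq(300, c("A", "C", "G", "T"))))
  tags <- data.frame(seq = mature, PS1 = 25L)
  cands <- suppressMessages(predict_novel(tags, genome))
  pass <- cands[cands$pass, ]
  expect_equal(nrow(pass), 1)
  expect_equal(pass$tag, mature)
  expect_equal(pass$arm, "5p")
  expect_lte(pass$mfe, -18)
  expect_gte(pass$space, 16)
  expect_lte(pass$bulge, 4)
  ## the independent validator agrees criterion by criterion
  val <- validate_hairpin(pass$precursor, mature, copies = 1L)
  expect_true(val$pass)
})

test_that("a tag with too many genome copies is rejected by the copy bound", {
  set.seed(410)
  mature <- "TGCACGTTCGATAGCTAGCTT"
  block <- mk_hairpin(mature, "5p")
  fill <- function() rand_seq(40, c("A", "C", "G", "T"))
  many <- paste(c(block, vapply(1:21, function(i) paste0(fill(), mature),
                                character(1)), fill()), collapse = "")
  genome <- c(chr1 = many)
  cands <- suppressMessages(predict_novel(data.frame(seq = mature,
                                                     PS1 = 5L), genome))
  expect_true(all(!cands$pass))
  expect_true(all(!cands$c_copies))
  expect_gt(cands$copies[1], 20)
})

test_that("candidates sharing a mature collapse into one ranked record", {
  set.seed(411)
  m1 <- "TGCACGTTCGATAGCTAGCTT"
  m2 <- "AGGTCCGTATTGCACATCGAT"
  genome <- c(chr1 = paste0(rand_seq(150, c("A", "C", "G", "T")),
                            mk_hairpin(m1, "5p"),
                            rand_seq(150, c("A", "C", "G", "T")),
                            mk_hairpin(m1, "5p"),
                            rand_seq(150, c("A", "C", "G", "T")),
                            mk_hairpin(m2, "3p"),
                            rand_seq(150, c("A", "C", "G", "T"))))
  tags <- data.frame(seq = c(m1, m2), PS1 = c(50L, 400L))
  cands <- suppressMessages(predict_novel(tags, genome))
  res <- dedupe_candidates(cands, tags)
  expect_equal(nrow(res$info), 2)
  ## highest-count mature gets the lowest index
  expect_equal(res$info$name[1], "novel-m0001-3p")
  expect_equal(res$info$tag_seq[1], m2)
  expect_equal(res$info$copies_on_reference[res$info$tag_seq == m1], 2L)
  ## naming is stable across repeated runs
  res2 <- dedupe_candidates(cands, tags)
  expect_identical(res$info, res2$info)
})

test_that("every novel miRNA reported from simulated data re-validates", {
  run <- small_run()
  sim <- small_sim()
  pass <- run$candidates[run$candidates$pass, ]
  expect_gt(nrow(pass), 0)
  for (r in seq_len(nrow(pass))) {
    val <- validate_hairpin(pass$precursor[r], pass$tag[r],
                            copies = pass$copies[r])
    expect_true(val$pass, info = pass$tag[r])
  }
  ## no tag is both known and novel
  expect_length(intersect(run$known$info$tag_seq, run$novel$info$tag_seq),
                0)
  ## all planted hairpins are recovered
  expect_true(all(sim$truth$hairpins$mature_dna %in%
                    run$novel$info$tag_seq))
})
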