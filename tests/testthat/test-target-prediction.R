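MIRNA <- "UAGAUCGAUUCAGAUCGACAU"  # 21 nt; G/U at many odd positions

# site with chosen per-position values (DNA, 5'->3' on the transcript);
# `changes` maps miRNA position -> "gu" or "mm"
mk_site <- function(mirna, changes = list()) {
  mv <- strsplit(mirna, "")[[1]]
  L <- length(mv)
  site <- strsplit(revcomp(mirna), "")[[1]]
  for (p in names(changes)) {
    pos <- as.integer(p)
    q <- L - pos + 1L
    site[q] <- if (changes[[p]] == "gu") {
      if (mv[pos] == "G") "T" else "G"   # needs G or U at pos
    } else {
      c(A = "C", C = "A", G = "A", U = "C")[[mv[pos]]]
    }
  }
  paste(site, collapse = "")
}

test_that("a perfect complement scores zero and passes every rule", {
  hit <- score_duplex(MIRNA, mk_site(MIRNA))
  expect_equal(hit$total_weighted, 0)
  expect_true(hit$rules_pass)
  expect_true(mfe_ratio_filter(hit))
  expect_equal(attr(mfe_ratio_filter(hit), "hit")$mfe_ratio, 1.0)
})

test_that("G:U wobbles count 0.5 and reject at the cleavage site when strict", {
  h <- score_duplex(MIRNA, mk_site(MIRNA, list(`15` = "gu")))
  expect_equal(h$total_weighted, 0.5)
  expect_true(h$rules_pass)
  ## position 10 of this miRNA is U, so a wobble is possible there
  h10 <- score_duplex(MIRNA, mk_site(MIRNA, list(`10` = "gu")))
  expect_equal(h10$mismatch_vector[10], 0.5)
  expect_false(h10$r4)
  expect_false(h10$rules_pass)
  lenient <- target_rules(cleavage_strict = FALSE)
  expect_true(score_duplex(MIRNA, mk_site(MIRNA, list(`10` = "gu")),
                           lenient)$rules_pass)
})

test_that("rule boundaries behave as stated", {
  ## five full mismatches exceed the total cap of 4
  five <- mk_site(MIRNA, list(`13` = "mm", `15` = "mm", `17` = "mm",
                              `19` = "mm", `21` = "mm"))
  h5 <- score_duplex(MIRNA, five)
  expect_equal(h5$total_weighted, 5)
  expect_false(h5$r1)
  ## eight wobbles total 4.0 and pass the cap (spread to avoid adjacency)
  gu_ok <- setdiff(which(strsplit(MIRNA, "")[[1]] %in% c("G", "U")),
                   c(10, 11))
  picks <- gu_ok[1:8]          # pairwise non-adjacent for this miRNA
  stopifnot(all(diff(picks) >= 2))
  ch <- stats::setNames(rep(list("gu"), 8), picks)
  h8 <- score_duplex(MIRNA, mk_site(MIRNA, ch))
  expect_equal(h8$total_weighted, 4)
  expect_true(h8$r1)
  ## three adjacent non-paired positions violate rule 2
  adj <- mk_site(MIRNA, list(`15` = "mm", `16` = "mm", `17` = "mm"))
  expect_false(score_duplex(MIRNA, adj)$r2)
  two_adj <- mk_site(MIRNA, list(`15` = "mm", `16` = "mm"))
  expect_true(score_duplex(MIRNA, two_adj)$r2)
  ## adjacent full mismatches inside positions 2-12 violate rule 3
  seed_adj <- mk_site(MIRNA, list(`4` = "mm", `5` = "mm"))
  expect_false(score_duplex(MIRNA, seed_adj)$r3)
  ## more than 2.5 weighted mismatches in 1-12 violate rule 5
  seed_heavy <- mk_site(MIRNA, list(`2` = "mm", `4` = "mm", `6` = "mm"))
  h <- score_duplex(MIRNA, seed_heavy)
  expect_equal(sum(h$mismatch_vector[1:12]), 3)
  expect_false(h$r5)
  expect_error(score_duplex(MIRNA, "ACGT"), "length")
  expect_error(score_duplex("ACGU", "ACGU"), "18-25")
})

test_that("score_duplex agrees with the plain-loop rule oracle", {
  set.seed(417)
  for (rep in 1:400) {
    L <- sample(18:25, 1)
    m <- rand_seq(L)
    site <- if (runif(1) < 0.5) {
      s <- strsplit(revcomp(m), "")[[1]]
      k <- sample(L, sample(0:6, 1))
      s[k] <- sample(c("A", "C", "G", "T"), length(k), replace = TRUE)
      paste(s, collapse = "")
    } else {
      rand_seq(L, c("A", "C", "G", "T"))
    }
    hit <- score_duplex(m, site)
    orc <- oracle_rule_check(m, site)
    expect_equal(hit$total_weighted, orc$total, info = paste(m, site))
    expect_equal(hit$rules_pass, orc$pass, info = paste(m, site))
  }
})

test_that("turning a wobble into a Watson-Crick pair never breaks a pass", {
  set.seed(418)
  for (rep in 1:100) {
    m <- rand_seq(21)
    s <- strsplit(revcomp(m), "")[[1]]
    k <- sample(21, sample(1:5, 1))
    s[k] <- sample(c("A", "C", "G", "T"), length(k), replace = TRUE)
    site <- paste(s, collapse = "")
    hit <- score_duplex(m, site)
    if (!hit$rules_pass) next
    gu_pos <- which(hit$mismatch_vector == 0.5)
    for (p in gu_pos) {
      s2 <- s
      s2[21 - p + 1] <- chartr("ACGU", "TGCA",
                               strsplit(m, "")[[1]][p])
      expect_true(score_duplex(m, paste(s2, collapse = ""))$rules_pass)
    }
  }
})

test_that("the energy-ratio boundary at 0.74 is inclusive", {
  hit <- score_duplex(MIRNA, mk_site(MIRNA))
  hit$mfe_perfect <- -30
  hit$mfe_site <- -22.20   # ratio 0.7400
  expect_true(mfe_ratio_filter(hit))
  hit$mfe_site <- -22.197  # ratio 0.7399
  expect_false(mfe_ratio_filter(hit))
  hit$mfe_perfect <- 0
  expect_warning(res <- mfe_ratio_filter(hit), "degenerate")
  expect_false(res)
})

test_that("transcriptome scanning finds planted sites and nothing on
           unrelated sequence, independent of transcript order", {
  set.seed(419)
  tx_bg <- stats::setNames(
    vapply(rep(400, 4), function(n) rand_seq(n, c("A", "C", "G", "T")),
           character(1)), paste0("g", 1:4))
  site <- mk_site(MIRNA, list(`15` = "gu"))
  with_site <- tx_bg
  substr(with_site[["g2"]], 101, 100 + nchar(site)) <- site
  hits <- scan_transcriptome(c(m1 = MIRNA), with_site)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$transcript, "g2")
  expect_equal(hits$window_start, 101)
  expect_equal(hits$site_start, 101 + nchar(MIRNA) - 1)
  expect_gte(hits$mfe_ratio, 0.74)
  ## reversing the transcript order leaves the hit set identical
  hits2 <- scan_transcriptome(c(m1 = MIRNA), rev(with_site))
  expect_equal(hits2[order(hits2$transcript), -1],
               hits[order(hits$transcript), -1])
  ## no complementary transcript, no hits
  expect_equal(nrow(scan_transcriptome(c(m1 = MIRNA), tx_bg)), 0)
})

test_that("planted simulation sites are all recovered by the scan", {
  sim <- small_sim()
  tg <- sim$truth$targets
  mirnas <- stats::setNames(chartr("T", "U", unique(tg$mirna_dna)),
                            unique(tg$mirna_dna))
  hits <- scan_transcriptome(mirnas, sim$bundle$transcripts)
  found <- paste(hits$mirna, hits$transcript)
  expect_true(all(paste(tg$mirna_dna, tg$gene) %in% found))
})
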