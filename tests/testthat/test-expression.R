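test_that("TPM follows count / total x 1e6 and is scale invariant", {
  counts <- matrix(c(1L, 0L, 999999L, 10L), nrow = 2,
                   dimnames = list(c("a", "b"), c("L1", "L2")))
  tpm <- tpm_normalize(counts, totals = c(1e6, 1e6))
  expect_identical(tpm["a", "L1"], 1.0)
  expect_identical(tpm["b", "L1"], 0.0)
  expect_identical(tpm["a", "L2"], 999999.0)
  expect_identical(tpm["b", "L2"], 10.0)
  expect_equal(tpm_normalize(counts * 2L, totals = c(2e6, 2e6)), tpm)
  ## column sums hit 1e6 when totals are the column sums
  expect_equal(unname(colSums(tpm_normalize(counts))), c(1e6, 1e6))
  expect_error(tpm_normalize(counts, totals = c(0, 1)), "zero-total")
})

test_that("FPKM follows count / kb / million mapped fragments", {
  counts <- matrix(c(100L, 100L), nrow = 2,
                   dimnames = list(c("g1", "g2"), "L1"))
  f <- fpkm_normalize(counts, lengths = c(1000, 2000), totals = 1e6)
  expect_identical(f["g1", "L1"], 100.0)
  expect_identical(f["g2", "L1"], 50.0)
  expect_equal(fpkm_normalize(matrix(0L, 1, 1, dimnames = list("g", "L")),
                              lengths = 500, totals = 1e6)[1, 1], 0)
  expect_error(fpkm_normalize(counts, lengths = c(1000, NA)), "lengths")
})

test_that("the exact test is symmetric and matches the binomial closed form", {
  expect_equal(nb_exact_test(c(5, 5, 5), c(5, 5, 5), dispersion = 0), 1.0)
  ## dispersion 0, (0) vs (20): p = 2 * (1/2)^20
  expect_equal(nb_exact_test(0L, 20L, dispersion = 0), 2 * 0.5^20)
  ## an all-zero feature is uninformative by convention
  expect_equal(nb_exact_test(c(0L, 0L, 0L), c(0L, 0L, 0L),
                             dispersion = 0.1), 1.0)
})

test_that("swapping group labels flips the fold change, not the p-value", {
  set.seed(412)
  a <- rnbinom(3, mu = 40, size = 20)
  b <- rnbinom(3, mu = 160, size = 20)
  expect_equal(nb_exact_test(a, b, 0.05), nb_exact_test(b, a, 0.05))
  counts <- rbind(f1 = c(a, b))
  colnames(counts) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  groups <- rep(c("A", "B"), each = 3)
  fwd <- call_de_mirnas(counts, colSums(counts) + 1000, groups,
                        c("A", "B"), dispersion = 0.05)
  rev <- call_de_mirnas(counts, colSums(counts) + 1000, groups,
                        c("B", "A"), dispersion = 0.05)
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$p, rev$p)
})

test_that("null p-values are near-uniform at dispersion zero", {
  set.seed(413)
  n <- 2000
  p <- vapply(seq_len(n), function(i) {
    x <- rpois(6, 150)
    nb_exact_test(x[1:3], x[4:6], dispersion = 0)
  }, numeric(1))
  ## KS against uniform, allowing for discreteness of the exact test
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p <= 0.05) - 0.05), 0.02)
})

test_that("method-of-moments dispersion recovers the simulated value", {
  sim <- simulate_mirna_counts(3000, mean_count = 300, dispersion = 0.08,
                               seed = 414)
  est <- estimate_common_dispersion(sim$counts, sim$groups)
  expect_lt(abs(est - 0.08), 0.02)
})

test_that("both calling thresholds must be met", {
  ## |log2FC| = 0.99 with tiny p, and |log2FC| = 2 with p = 0.06: neither
  ## is called
  tpm_means <- function(lfc) {
    base <- 400
    c(rep(base, 3), rep(base * 2^lfc, 3))
  }
  mk <- function(mu, disp = 1e-8) {
    counts <- rbind(f1 = as.integer(round(mu)))
    colnames(counts) <- c("A1", "A2", "A3", "B1", "B2", "B3")
    counts
  }
  groups <- rep(c("A", "B"), each = 3)
  totals <- rep(1e6, 6)
  near <- call_de_mirnas(mk(tpm_means(0.99)), totals, groups, c("A", "B"),
                         dispersion = 0)
  expect_lt(near$p, 0.05)
  expect_false(near$called)
  weak <- call_de_mirnas(mk(c(100, 100, 100, 120, 120, 120)), totals,
                         groups, c("A", "B"), dispersion = 1.5)
  expect_gt(weak$p, 0.05)
  expect_true(abs(weak$log2fc) < 1 || !weak$called)
  strong <- call_de_mirnas(mk(tpm_means(2)), totals, groups, c("A", "B"),
                           dispersion = 0)
  expect_true(strong$called)
})

test_that("genes are called on FDR while miRNAs use the raw p", {
  ## three p-values 0.01/0.02/0.03 get BH FDRs 0.03/0.03/0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(p.adjust(0.04, "BH"), 0.04)
  set.seed(415)
  counts <- rbind(g1 = c(50L, 55L, 48L, 400L, 420L, 380L),
                  g2 = c(100L, 90L, 110L, 95L, 105L, 100L))
  colnames(counts) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  de <- call_degs(counts, lengths = c(1000, 1000),
                  groups = rep(c("A", "B"), each = 3),
                  comparison = c("A", "B"), totals = rep(1e6, 6),
                  dispersion = 0.05)
  expect_true(de$called[1])
  expect_false(de$called[2])
  expect_true(all(de$fdr >= de$p - 1e-12))
})

test_that("the exact test tracks edgeR on shared data", {
  skip_if_not_installed("edgeR")
  sim <- simulate_mirna_counts(300, mean_count = 150, dispersion = 0.05,
                               effect_log2fc = 2, de_fraction = 0.2,
                               seed = 416)
  p_own <- vapply(seq_len(nrow(sim$counts)), function(i) {
    nb_exact_test(sim$counts[i, 1:3], sim$counts[i, 4:6], 0.05)
  }, numeric(1))
  dge <- edgeR::DGEList(counts = sim$counts,
                        group = factor(sim$groups),
                        lib.size = rep(mean(colSums(sim$counts)), 6))
  et <- edgeR::exactTest(dge, dispersion = 0.05)
  p_edger <- et$table$PValue
  expect_gt(cor(log10(p_own + 1e-300), log10(p_edger + 1e-300),
                method = "spearman"), 0.98)
  expect_equal(mean((p_own <= 0.05) == (p_edger <= 0.05)), 1,
               tolerance = 0.03)
})

test_that("relative expression follows 2^-ddCt with the calibrator at 1", {
  ct <- expand.grid(sample = c("PS", "TS"), replicate = 1:3,
                    stringsAsFactors = FALSE)
  ct_t <- transform(ct, assay = "miR1",
                    ct = ifelse(sample == "PS", 24, 23) +
                      c(0.05, -0.05, 0)[replicate])
  ct_r <- transform(ct, assay = "rRNA5.8S", ct = 15)
  tab <- rbind(ct_t, ct_r)
  res <- delta_delta_ct(tab, "miR1", "rRNA5.8S", "PS")
  expect_equal(res$rel_expr[res$sample == "PS"], 1.0)
  expect_equal(res$rel_expr[res$sample == "TS"], 2.0, tolerance = 1e-6)
  ## ddCt of 3.32 is about a 10-fold reduction
  tab10 <- rbind(transform(ct, assay = "miR1",
                           ct = ifelse(sample == "PS", 20, 23.32)),
                 ct_r)
  res10 <- delta_delta_ct(tab10, "miR1", "rRNA5.8S", "PS")
  expect_equal(res10$rel_expr[res10$sample == "TS"], 2^-3.32,
               tolerance = 1e-9)
  expect_equal(round(res10$rel_expr[res10$sample == "TS"], 1), 0.1)
  expect_error(delta_delta_ct(tab[tab$assay != "rRNA5.8S", ], "miR1",
                              "rRNA5.8S", "PS"), "reference")
})
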