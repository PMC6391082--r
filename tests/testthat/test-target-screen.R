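test_that("mature miRNA sequences are validated and the seed is positions 2-8", {
  mi <- mature_mirna("ACGUACGUACGUACGUACGUAC")
  expect_equal(nchar(mi$seed), 7L)
  expect_equal(mi$seed, substr(mi$sequence, 2, 8))
  expect_equal(mature_mirna("acgtacgtacgtacgtacgtac")$sequence,
               "ACGUACGUACGUACGUACGUAC")
  expect_error(mature_mirna("ACGUACGX__GUACGUACGUAC"), "non-ACGU")
  expect_error(mature_mirna("ACGU"), "18-26")
})

test_that("seed scanning finds embedded sites with the right class and start", {
  mirna <- mature_mirna("UCAUAAAGUAGAAAGCACUACU")
  core  <- tregmir:::rna_revcomp(substr(mirna$sequence, 2, 7))   # vs positions 2-7
  site7 <- tregmir:::rna_revcomp(substr(mirna$sequence, 2, 8))   # vs positions 2-8

  # a UTR free of the seed complement yields nothing
  set.seed(1)
  repeat {
    bg <- random_rna_str(30L)
    if (!grepl(core, bg, fixed = TRUE)) break
  }
  expect_equal(nrow(scan_seed_sites(bg, mirna, gene = "g")), 0L)

  # 7mer-m8 embedded at offset 11 (no A downstream)
  utr <- paste0(substr(bg, 1, 10), site7, "C", substr(bg, 12, 30))
  hit <- scan_seed_sites(utr, mirna, gene = "g")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 11L)
  expect_equal(hit$end, 17L)
  expect_equal(hit$match_class, "7mer-m8")

  # appending an A opposite position 1 upgrades it to 8mer
  utr8 <- paste0(substr(bg, 1, 10), site7, "A", substr(bg, 12, 30))
  expect_equal(scan_seed_sites(utr8, mirna, gene = "g")$match_class, "8mer")

  # core alone is a 6mer; core + A is 7mer-A1
  utr6 <- paste0("GG", core, "C", substr(bg, 1, 20))
  got6 <- scan_seed_sites(utr6, mirna, gene = "g")
  expect_equal(got6$match_class, "6mer")
  expect_equal(got6$start, 3L)
  utrA1 <- paste0("GG", core, "A", substr(bg, 1, 20))
  expect_equal(scan_seed_sites(utrA1, mirna, gene = "g")$match_class, "7mer-A1")

  # DNA input is transcribed before matching
  dna <- gsub("U", "T", utr8)
  expect_equal(scan_seed_sites(dna, mirna, gene = "g")$match_class, "8mer")

  expect_error(scan_seed_sites("ACGUNNN", mirna), "non-ACGU")
})

test_that("scanner agrees with naive substring search on 1,000 random pairs", {
  set.seed(99)
  for (i in 1:1000) {
    mirna <- mature_mirna(random_mirna_str())
    core <- tregmir:::rna_revcomp(substr(mirna$sequence, 2, 7))
    utr <- random_rna_str(sample(20:120, 1L))
    got <- scan_seed_sites(utr, mirna, gene = "g")
    # core start implied by each reported site (m8 classes shift by one)
    got_cores <- got$start + ifelse(got$match_class %in% c("8mer", "7mer-m8"), 1L, 0L)
    expect_identical(sort(got_cores), sort(oracle_core_positions(utr, core)),
                     label = paste("pair", i))
  }
})

test_that("substituting the seed-pairing bases kills every site class at that locus", {
  set.seed(123)
  for (i in 1:25) {
    mirna <- mature_mirna(random_mirna_str())
    utr <- random_rna_str(80L)
    site7 <- tregmir:::rna_revcomp(substr(mirna$sequence, 2, 8))
    p <- sample(5:60, 1L)
    substr(utr, p, p + 6L) <- site7
    hits <- scan_seed_sites(utr, mirna, gene = "g")
    expect_true(any(hits$start == p))
    # substitute the 6 bases pairing with seed positions 2-7 (purine<->pyrimidine
    # swap, which can never restore complementarity)
    core_start <- p + 1L
    mut <- utr
    for (q in core_start:(core_start + 5L)) {
      substr(mut, q, q) <- c(A = "C", C = "A", G = "U", U = "G")[[substr(mut, q, q)]]
    }
    hits_mut <- scan_seed_sites(mut, mirna, gene = "g")
    expect_false(any(hits_mut$start %in% c(p, core_start)))
  }
})

test_that("AGO support requires full containment and matches the quadratic oracle", {
  site <- data.frame(gene = "g", start = 11L, end = 17L, match_class = "7mer-m8",
                     ago_supported = NA)
  expect_true(mark_ago_support(site, data.frame(gene = "g", start = 1, end = 50))$ago_supported)
  expect_false(mark_ago_support(site, data.frame(gene = "g", start = 15, end = 50))$ago_supported)
  expect_false(mark_ago_support(site, data.frame(gene = "other", start = 1, end = 50))$ago_supported)
  expect_false(mark_ago_support(site, data.frame(gene = character(), start = numeric(),
                                                 end = numeric()))$ago_supported)

  set.seed(5)
  sites <- data.frame(gene = sample(c("a", "b", "c"), 100, replace = TRUE),
                      start = sample(1:200, 100, replace = TRUE))
  sites$end <- sites$start + 6L
  sites$match_class <- "7mer-m8"; sites$ago_supported <- NA
  ivs <- data.frame(gene = sample(c("a", "b", "c"), 40, replace = TRUE),
                    start = sample(1:200, 40, replace = TRUE))
  ivs$end <- ivs$start + sample(5:60, 40, replace = TRUE)
  expect_equal(mark_ago_support(sites, ivs)$ago_supported,
               oracle_ago_flags(sites, ivs))
})

test_that("expression filter applies strict fold and p thresholds per comparison", {
  expect_equal(expression_filter(data.frame(gene = character(), comparison = character(),
                                            log2fc = numeric(), p_value = numeric()),
                                 "KO_vs_WT_Treg", "up"), character())
  st <- data.frame(gene = c("A", "B", "C"), comparison = "KO_vs_WT_Treg",
                   log2fc = c(1.5, 0.8, 2.0), p_value = c(0.01, 0.01, 0.20))
  expect_equal(expression_filter(st, "KO_vs_WT_Treg", "up"), "A")
  # boundary: log2fc exactly 1.0 at 2-fold is excluded (strict ">2-fold")
  st2 <- data.frame(gene = "E", comparison = "KO_vs_WT_Treg",
                    log2fc = 1.0, p_value = 1e-6)
  expect_equal(expression_filter(st2, "KO_vs_WT_Treg", "up"), character())
  # p exactly alpha is excluded
  st3 <- data.frame(gene = "F", comparison = "KO_vs_WT_Treg",
                    log2fc = 3, p_value = 0.05)
  expect_equal(expression_filter(st3, "KO_vs_WT_Treg", "up"), character())
  # down direction uses the mirrored threshold
  st4 <- data.frame(gene = c("G", "H"), comparison = "Treg_vs_Teff",
                    log2fc = c(-1.4, -0.9), p_value = 0.01)
  expect_equal(expression_filter(st4, "Treg_vs_Teff", "down"), "G")
  expect_error(expression_filter(st, "nonsense", "up"), "Unknown comparison")
})

test_that("the three-criteria screen intersects evidence and recovers planted targets only", {
  # pairwise-disjoint evidence yields an empty candidate set
  mirna <- "UCAUAAAGUAGAAAGCACUACU"
  site7 <- tregmir:::rna_revcomp(substr(mature_mirna(mirna)$sequence, 2, 8))
  utrs <- c(siteonly = paste0("GGGG", site7, "AGGGGGGGGGGG"))
  ago <- data.frame(gene = "siteonly", start = 1, end = 30)
  st <- rbind(
    data.frame(gene = c("uponly", "siteonly"), comparison = "KO_vs_WT_Treg",
               log2fc = c(2, 0), p_value = c(0.001, 0.9)),
    data.frame(gene = c("uponly", "siteonly"), comparison = "Treg_vs_Teff",
               log2fc = 0, p_value = 0.9))
  cand <- run_screen(utrs, mirna, ago, st)
  expect_length(cand$genes, 0L)

  # planted cohort: exactly the planted genes, zero decoy leakage
  for (seed in 1:20) {
    co <- gen_screen_cohort(seed)
    stats <- cohort_de_stats(co)
    got <- run_screen(co$utrs, co$mirna, co$ago, stats)
    expect_identical(got$genes, co$truth$planted_targets,
                     label = paste("seed", seed))
    expect_true(all(vapply(got$evidence, function(e)
      nrow(e$sites) >= 1L && all(e$sites$ago_supported), logical(1L))))
  }
})

test_that("screen output is monotone in thresholds and invariant to record order", {
  co <- gen_screen_cohort(31)
  stats <- cohort_de_stats(co)
  base <- run_screen(co$utrs, co$mirna, co$ago, stats)$genes
  relaxed_a <- run_screen(co$utrs, co$mirna, co$ago, stats, alpha = 0.2)$genes
  relaxed_f <- run_screen(co$utrs, co$mirna, co$ago, stats, fold_threshold = 1.2)$genes
  expect_true(all(base %in% relaxed_a))
  expect_true(all(base %in% relaxed_f))
  tight <- run_screen(co$utrs, co$mirna, co$ago, stats, fold_threshold = 3.5)$genes
  expect_true(all(tight %in% base))

  set.seed(17)
  perm_stats <- stats[sample(nrow(stats)), ]
  perm_utrs <- co$utrs[sample(length(co$utrs))]
  perm_ago <- co$ago[sample(nrow(co$ago)), ]
  expect_identical(run_screen(perm_utrs, co$mirna, perm_ago, perm_stats)$genes, base)
})

test_that("genes observed in only one comparison are dropped with a warning", {
  mirna <- "UCAUAAAGUAGAAAGCACUACU"
  site7 <- tregmir:::rna_revcomp(substr(mature_mirna(mirna)$sequence, 2, 8))
  utrs <- c(halfgene = paste0("GGGG", site7, "AGGGGGGGGGGG"))
  ago <- data.frame(gene = "halfgene", start = 1, end = 30)
  st <- data.frame(gene = "halfgene", comparison = "KO_vs_WT_Treg",
                   log2fc = 3, p_value = 1e-5)
  expect_warning(cand <- run_screen(utrs, mirna, ago, st), "one comparison")
  expect_length(cand$genes, 0L)
})

test_that("moderated DE recovers exact ratios, planted folds, and agrees with an independent fit", {
  genes <- paste0("g", 1:50)
  expr <- matrix(stats::rlnorm(50 * 8, log(50), 0.3), 50, 8,
                 dimnames = list(genes, NULL))
  same <- cbind(expr[, 1:4], expr[, 1:4])
  de0 <- simple_moderated_de(same, rep(c("A", "B"), each = 4))
  expect_equal(de0$log2fc, rep(0, 50))

  scaled <- cbind(expr[, 1:4] * 4, expr[, 1:4])
  de4 <- simple_moderated_de(scaled, rep(c("A", "B"), each = 4))
  expect_equal(de4$log2fc, rep(2, 50))

  expect_error(simple_moderated_de(expr[, 1:3, drop = FALSE], c("A", "B", "B")),
               ">= 2 samples")

  # planted 2.5-fold at n = 5/group, known sigma: mean recovered log2fc
  # within +/-0.2 of log2(2.5) over 20 seeds
  recovered <- vapply(1:20, function(seed) {
    set.seed(seed + 4000)
    m <- matrix(2^stats::rnorm(200 * 10, 0, 0.25), 200, 10,
                dimnames = list(paste0("g", 1:200), NULL))
    m[, 1:5] <- m[, 1:5] * 2.5
    mean(simple_moderated_de(m * 100, rep(c("A", "B"), each = 5))$log2fc)
  }, numeric(1L))
  expect_true(all(abs(recovered - log2(2.5)) < 0.2))

  # cross-check p-value ordering against limma on one cohort
  if (requireNamespace("limma", quietly = TRUE)) {
    co <- gen_screen_cohort(8, n_genes = 100L)
    ours <- simple_moderated_de(co$expr_ko, co$groups_ko)
    design <- stats::model.matrix(~ factor(co$groups_ko, levels = c("WT", "KO")))
    fit <- limma::eBayes(limma::lmFit(log2(co$expr_ko), design))
    theirs <- fit$p.value[, 2L]
    expect_gt(stats::cor(log10(ours$p_value), log10(theirs), method = "spearman"), 0.9)
  }
})
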