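test_that("ld_r2 matches the direct correlation formula", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1)  # perfect negative
  a <- c(0, 1, 2, 1, 0); b <- c(0, 0, 2, 1, 1)
  expect_equal(ld_r2(a, b), cor(a, b)^2)
  expect_warning(z <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "zero variance")
  expect_equal(z, 0)
})

test_that("greedy clumping keeps the most significant variant per clump", {
  ## two perfectly correlated variants 1 kb apart: better p wins
  x <- rbinom(50, 2, 0.4)
  dosage <- cbind(x, x, rbinom(50, 2, 0.4))
  v <- toy_variants(rep("chr1", 3), c(1000, 2000, 5e6),
                    pvalue = c(1e-8, 1e-6, 0.5))
  keep <- greedy_clump(v, dosage)
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  ## mutually uncorrelated variants are all retained
  set.seed(2)
  d2 <- matrix(rbinom(300, 2, 0.5), 100)
  v2 <- toy_variants(rep("chr1", 3), c(1, 2, 3),
                     pvalue = c(0.1, 0.2, 0.3))
  expect_true(all(greedy_clump(v2, d2)))
})

test_that("greedy clumping equals the brute-force reference on synthetic panels", {
  for (s in 1:8) {
    cfg <- sim_config(n_individuals = 250, n_variants = 200,
                      n_genes = 25, ld_rho = 0.9, seed = s)
    g <- simulate_genotypes(cfg)
    ss <- simulate_gwas(cfg, g)
    v <- suppressMessages(harmonize_sumstats(ss, g$map))
    got <- greedy_clump(v, g$dosage)
    want <- naive_clump(v, g$dosage)
    expect_identical(got, want)
  }
})

test_that("effect scaling matches the percent-weight convention", {
  w <- matrix(c(0.884, 0.05, 0.066), 1,
              dimnames = list("LINC-like", c("OPC", "microglia",
                                             "astrocyte")))
  v <- data.frame(id = "2:103835819", beta = -0.0603,
                  gene_id = "LINC-like", stringsAsFactors = FALSE)
  sv <- scale_weights(v, w)
  expect_equal(sv$scaled_OPC, -0.0603 * 88.4)
  expect_equal(round(sv$scaled_OPC, 1), -5.3)
  expect_equal(sv$scaled_full, -0.0603)
  ## weight 0 zeroes the scaled effect; weight 1 gives 100 x beta
  w2 <- matrix(c(1, 0), 1, dimnames = list("g", c("a", "b")))
  v2 <- data.frame(id = "v", beta = 0.2, gene_id = "g")
  sv2 <- scale_weights(v2, w2)
  expect_equal(sv2$scaled_a, 20)
  expect_equal(sv2$scaled_b, 0)
  ## unmapped gene: NA in cell scores, kept in full
  v3 <- data.frame(id = "v", beta = 0.2, gene_id = "missing")
  sv3 <- suppressMessages(scale_weights(v3, w2))
  expect_true(is.na(sv3$scaled_a))
  expect_equal(sv3$scaled_full, 0.2)
})

test_that("threshold subsets are strict and nested", {
  p <- c(0.04, 4e-3, 4e-4, 4e-5, 4e-6, 4e-7, 4e-8, 0.5, 0.05)
  v <- toy_variants(rep("chr1", 9), seq_len(9) * 1e6, pvalue = p)
  sets <- threshold_sets(v, rep(TRUE, 9))
  expect_equal(lengths(sets), setNames(7:1, paste0("PRS", 1:7)))
  expect_true(1 %in% sets$PRS1 && !(1 %in% sets$PRS2))  # p = 0.04
  expect_true(all(7 == Reduce(intersect, sets)))        # p = 4e-8 in all
  expect_false(9 %in% sets$PRS1)                        # 0.05 not < 0.05
  for (k in 2:7) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
})

test_that("scoring sums dosage times effect with EAF imputation", {
  dosage <- rbind(c(0, 1, 2), c(1, NA, 0), c(2, 1, 1), c(1, 0, 2))
  v <- toy_variants(rep("chr1", 3), c(1, 2, 3), pvalue = rep(0.01, 3),
                    beta = c(0.5, -1, 2))
  v$scaled_full <- v$beta
  got <- score_individuals(dosage, v, "scaled_full")
  ## missing dosage -> 2 x EAF among non-missing = 2 * (2/6) = 2/3
  imput <- 2 * mean(dosage[-2, 2]) / 2
  want <- c(0 * 0.5 + 1 * -1 + 2 * 2,
            1 * 0.5 + imput * -1 + 0 * 2,
            2 * 0.5 + 1 * -1 + 1 * 2,
            1 * 0.5 + 0 * -1 + 2 * 2)
  expect_equal(got, want)
  ## single-variant dosages scale linearly; all-zero betas give zero
  v1 <- v[1, ]; v1$scaled_full <- 3
  expect_equal(score_individuals(dosage, v1, "scaled_full"),
               3 * dosage[, 1])
  expect_error(score_individuals(dosage, v, "scaled_full", integer(0)),
               "empty")
})

test_that("standardization gives exact z-scores and rejects constants", {
  z <- standardize_scores(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_error(standardize_scores(rep(2, 5), "colX"), "colX")
  set.seed(3)
  x <- rnorm(50)
  z2 <- standardize_scores(x)
  expect_lt(abs(mean(z2)), 1e-10)
  expect_lt(abs(sd(z2) - 1), 1e-10)
})

test_that("an all-ones weight matrix reproduces the full PRS exactly", {
  cfg <- small_cfg(seed = 21)
  co <- simulate_cohort(cfg)
  harm <- suppressMessages(harmonize_sumstats(co$sumstats,
                                              co$genotypes$map))
  harm <- suppressMessages(map_nearest_gene(harm, co$annotation))
  ones <- matrix(1, nrow = cfg$n_genes, 1,
                 dimnames = list(cfg$gene_ids, "all"))
  vt <- scale_weights(harm, ones)
  sm <- suppressWarnings(build_scores(co$genotypes$dosage, vt))
  for (k in 1:7) {
    a <- sm[, paste0("all_PRS", k)]
    b <- sm[, paste0("full_PRS", k)]
    expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
  }
})

test_that("renormalized gene weights leave standardized cell scores unchanged", {
  cfg <- small_cfg(seed = 22)
  co <- simulate_cohort(cfg)
  w <- cell_weights(co$expression$counts,
                    co$expression$cell_meta$cell_type)
  harm <- suppressMessages(harmonize_sumstats(co$sumstats,
                                              co$genotypes$map))
  harm <- suppressMessages(map_nearest_gene(harm, co$annotation))
  vt1 <- scale_weights(harm, w)
  ## scaling a row and renormalizing is a no-op
  w2 <- unclass(w)
  w2 <- w2 / rowSums(w2)
  vt2 <- scale_weights(harm, w2)
  s1 <- suppressWarnings(build_scores(co$genotypes$dosage, vt1))
  s2 <- suppressWarnings(build_scores(co$genotypes$dosage, vt2))
  expect_equal(unclass(s1), unclass(s2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("restricted PRS keeps only variants near cell-specific genes", {
  ann <- data.frame(gene_id = c("gM", "gO"), chrom = c("chr1", "chr2"),
                    start = c(5e6, 5e6), end = c(5e6 + 1e4, 5e6 + 1e4),
                    stringsAsFactors = FALSE)
  w <- rbind(gM = c(microglia = 0.9, OPC = 0.1),
             gO = c(microglia = 0.3, OPC = 0.7))
  set.seed(5)
  dosage <- matrix(rbinom(100 * 4, 2, 0.4), 100)
  v <- toy_variants(c("chr1", "chr1", "chr2", "chr1"),
                    c(5.5e6, 7e6, 5.5e6, 4.5e6),
                    pvalue = c(1e-4, 1e-3, 1e-5, 1e-2),
                    beta = c(0.3, 0.2, 0.4, 0.1))
  r <- suppressWarnings(restricted_prs(dosage, v, w, ann, tau = 0.5))
  nv <- attr(r, "n_variants")
  ## microglia: variants 1 and 4 within 1 Mb of gM (2 is 2 Mb away)
  expect_equal(unname(nv["microglia_rPRS1"]), 2L)
  ## OPC: only variant 3 near gO
  expect_equal(unname(nv["OPC_rPRS1"]), 1L)
  ## brute-force interval check
  near_gm <- abs(pmax(ann$start[1] - v$pos, v$pos - ann$end[1], 0)) <= 1e6 &
    v$chrom == "chr1"
  expect_equal(sum(near_gm), 2L)
  ## tau = 1 with no perfectly specific gene: nothing produced
  warns <- testthat::capture_warnings(
    r2 <- restricted_prs(dosage, v, w, ann, tau = 1))
  expect_match(warns, "no genes pass", all = FALSE)
  expect_null(r2)
})
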