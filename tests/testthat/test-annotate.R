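test_that("HWE chi-square test matches exact cases", {
  expect_equal(hwe_test(25, 50, 25), 1)    # exact HWE proportions
  ## no heterozygotes: chi-square equals n, p astronomically small
  expect_lt(hwe_test(50, 0, 50), 5e-8)
  expect_equal(hwe_test(50, 0, 50),
               pchisq(100, df = 1, lower.tail = FALSE))
  expect_equal(hwe_test(100, 0, 0), 1)     # monomorphic convention
  expect_error(hwe_test(0, 0, 0), "positive")
  ## vectorized
  expect_equal(hwe_test(c(25, 100), c(50, 0), c(25, 0)), c(1, 1))
})

test_that("qc_filter drops exactly the offending variants with reasons", {
  set.seed(1)
  n <- 400
  ok <- rbinom(n, 2, 0.3)
  low_maf <- rbinom(n, 2, 0.02)
  bad_hwe <- sample(c(0, 2), n, replace = TRUE)      # no heterozygotes
  bad_call <- ok; bad_call[1:20] <- NA               # call rate 0.95
  chrx <- ok
  dosage <- cbind(ok, low_maf, bad_hwe, bad_call, chrx)
  variants <- data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chrX"),
    id = paste0("v", 1:5),
    ref = c("A", "A", "A", "A", "A"),
    alt = c("G", "G", "G", "G", "G"), stringsAsFactors = FALSE)
  res <- qc_filter(dosage, variants)
  expect_equal(res$retained, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(res$report$reason,
               c(NA, "maf", "hwe", "call_rate", "autosomal"))
  ## idempotence: filtering the retained set changes nothing
  res2 <- qc_filter(dosage[, res$retained, drop = FALSE],
                    variants[res$retained, , drop = FALSE])
  expect_true(all(res2$retained))
})

test_that("harmonization keeps, flips, and drops correctly", {
  map <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                    id = paste0("g", 1:4),
                    ref = c("G", "A", "A", "C"),
                    alt = c("A", "G", "T", "G"), stringsAsFactors = FALSE)
  ss <- data.frame(CHR = "1", POS = c(100, 200, 300, 400),
                   ID = paste0("s", 1:4),
                   EA = c("A", "A", "A", "A"),
                   OA = c("G", "G", "T", "C"),
                   BETA = c(0.2, 0.2, 0.3, 0.1), P = rep(0.01, 4),
                   stringsAsFactors = FALSE)
  h <- suppressMessages(harmonize_sumstats(ss, map))
  ## v1: EA matches ALT -> unchanged; v2: EA matches REF -> flipped
  expect_equal(h$beta[h$id == "g1"], 0.2)
  expect_equal(h$beta[h$id == "g2"], -0.2)
  expect_true(h$flipped[h$id == "g2"])
  ## v3: A/T ambiguous but matches literally (EA = ref) -> kept flipped
  expect_equal(h$beta[h$id == "g3"], -0.3)
  ## v4: A/C does not match C/G genotype -> dropped
  expect_false("g4" %in% h$id)
  expect_equal(attr(h, "dropped")$reason, "allele_mismatch")
  ## ambiguous pairs removed under drop_ambiguous
  h2 <- suppressMessages(harmonize_sumstats(ss, map,
                                            drop_ambiguous = TRUE))
  expect_false("g3" %in% h2$id)
  ## duplicates are an error
  expect_error(harmonize_sumstats(rbind(ss, ss[1, ]), map), "duplicate")
})

test_that("flipping alleles twice restores the original effect", {
  map <- data.frame(chrom = "chr1", pos = 100, id = "g1",
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  ss <- data.frame(CHR = "chr1", POS = 100, ID = "s1", EA = "A",
                   OA = "G", BETA = 0.4, P = 0.5,
                   stringsAsFactors = FALSE)
  h1 <- harmonize_sumstats(ss, map)
  ## EA is the REF allele, so the effect is re-expressed for ALT
  expect_equal(h1$beta, -0.4)
  ## flipping the harmonized record back produces the same original
  ## representation, so harmonizing again returns the identical beta
  ss2 <- data.frame(CHR = h1$chrom, POS = h1$pos, ID = h1$id,
                    EA = h1$oa, OA = h1$ea, BETA = -h1$beta,
                    P = h1$pvalue, stringsAsFactors = FALSE)
  h2 <- harmonize_sumstats(ss2, map)
  expect_equal(h2$beta, h1$beta)
})

test_that("nearest-gene mapping agrees with exhaustive search", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(100, 500, 50),
                    end = c(200, 600, 80), stringsAsFactors = FALSE)
  v <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
                  pos = c(150, 350, 650, 10, 99))
  m <- suppressMessages(map_nearest_gene(v, ann))
  expect_equal(m$gene_id, c("gA", "gA", "gB", "gC", NA))
  expect_equal(m$gene_distance, c(0, 150, 50, 40, NA))
  ## pos 350 is exactly midway between gA end (200) and gB start (500)
  ## -> tie broken to the smaller start (gA)

  ## property: random toys match the brute-force oracle
  set.seed(9)
  for (rep in 1:30) {
    k <- sample(2:10, 1)
    st <- sort(sample.int(5000, k))
    ann_r <- data.frame(gene_id = sprintf("g%02d", sample(k)),
                        chrom = "chr1", start = st,
                        end = st + sample(50:200, k, replace = TRUE),
                        stringsAsFactors = FALSE)
    pos <- sample.int(6000, 40)
    got <- map_nearest_gene(data.frame(chrom = "chr1", pos = pos),
                            ann_r)
    for (i in seq_along(pos)) {
      want <- naive_nearest("chr1", pos[i], ann_r)
      expect_equal(got$gene_id[i], want$gene)
      expect_equal(got$gene_distance[i], want$d)
    }
  }
})

test_that("snp-gene tables override positional mapping", {
  v <- data.frame(chrom = "chr1", pos = c(1, 2, 3),
                  id = c("v1", "v2", "v3"),
                  gene_id = c("gX", "gX", "gX"),
                  gene_distance = c(0, 0, 0), stringsAsFactors = FALSE)
  tab <- data.frame(id = c("v1", "v3"), gene_id = c("gA", "gB"),
                    stringsAsFactors = FALSE)
  out <- apply_snp_gene_table(v, tab)
  expect_equal(out$gene_id, c("gA", NA, "gB"))
  out2 <- apply_snp_gene_table(v, data.frame(id = character(0),
                                             gene_id = character(0)))
  expect_true(all(is.na(out2$gene_id)))
})

test_that("APOE mask removes exactly the flanked window, inclusive", {
  v <- data.frame(chrom = c("chr19", "chr19", "chr19", "chr19", "chr1"),
                  pos = c(44905796, 43905795, 43905796, 44909393 + 1e6,
                          44905796))
  m <- apoe_mask(v)
  expect_equal(nrow(m$dropped), 3L)
  expect_true(44905796 %in% m$dropped$pos[m$dropped$chrom == "chr19"])
  expect_true(43905795 %in% m$retained$pos)       # 1 bp outside
  expect_true(43905796 %in% m$dropped$pos)        # boundary inclusive
  expect_true("chr1" %in% m$retained$chrom)       # wrong chromosome
  expect_equal(nrow(m$retained) + nrow(m$dropped), nrow(v))
})
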