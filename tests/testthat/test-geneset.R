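# GWAS scan, window mapping, best-SNP scores, confound correction and the
# permutation enrichment test.

test_that("the association scan is calibrated and finds planted effects", {
  withr::with_seed(90, {
    n <- 600; m <- 3000
    maf <- runif(m, 0.1, 0.5)
    G <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
    colnames(G) <- sprintf("rs%06d", 1:m)
    y0 <- rnorm(n)
    gw0 <- gwas_scan(y0, G)
    expect_gt(ks.test(gw0$p, "punif")$p.value, 0.01)
    # one large-effect SNP dominates the scan
    y1 <- 0.5 * scale(G[, 7]) + rnorm(n, 0, 0.8)
    gw1 <- gwas_scan(drop(y1), G)
    expect_identical(gw1$snp[which.min(gw1$p)], "rs000007")
    expect_gt(gw1$beta[gw1$snp == "rs000007"], 0)
    # strong hits carry the planted sign
    strong <- gw1[gw1$p < 1e-4 & gw1$snp == "rs000007", ]
    expect_true(all(strong$beta > 0))
    # monomorphic SNPs are dropped from the output
    G2 <- cbind(G[, 1:10], mono = 2L)
    expect_false("mono" %in% gwas_scan(y0, G2)$snp)
  })
})

test_that("SNP-to-gene windows respect the BED/1-based boundary conventions", {
  genes <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                      gene = "G1", stringsAsFactors = FALSE)
  flank <- 35L  # kb
  mk_var <- function(bp) data.frame(snp = paste0("rs", bp), chrom = "chr1",
                                    bp = bp, stringsAsFactors = FALSE)
  # interior SNP maps
  expect_identical(map_snps_to_genes(mk_var(1500L), genes, flank)$n_mapped, 1L)
  # window start in 1-based coordinates is start0 - flank + 1
  lo <- 1000L - 35000L + 1L
  expect_identical(map_snps_to_genes(mk_var(lo), genes, flank)$n_mapped, 1L)
  expect_identical(map_snps_to_genes(mk_var(lo - 1L), genes, flank)$n_mapped, 0L)
  # window end is end0 + flank (half-open upstream)
  hi <- 2000L + 35000L
  expect_identical(map_snps_to_genes(mk_var(hi), genes, flank)$n_mapped, 1L)
  expect_identical(map_snps_to_genes(mk_var(hi + 1L), genes, flank)$n_mapped, 0L)
  # zero flank, intergenic SNP stays unmapped; chrom mismatches are counted
  expect_identical(map_snps_to_genes(mk_var(2500L), genes, 0)$n_mapped, 0L)
  v <- mk_var(1500L); v$chrom <- "chr9"
  out <- map_snps_to_genes(v, genes, flank)
  expect_identical(out$unmapped_chroms, "chr9")
})

test_that("gene scores take the best mapped SNP p-value", {
  gwas <- data.frame(snp = c("a", "b", "c"), p = c(0.5, 0.01, 0.2))
  mapping <- list(mapping = data.frame(snp = c("a", "b", "c", "c"),
                                       gene = c("G1", "G1", "G1", "G2")))
  gs <- gene_scores(gwas, mapping)
  expect_equal(gs$raw_p[gs$gene == "G1"], 0.01)
  expect_equal(gs$raw_p[gs$gene == "G2"], 0.2)
  expect_identical(gs$n_snps[gs$gene == "G1"], 3L)
  # invariant to SNP order
  mapping2 <- list(mapping = mapping$mapping[c(4, 2, 3, 1), ])
  expect_equal(gene_scores(gwas, mapping2)[order(gs$gene), "raw_p"],
               gs[order(gs$gene), "raw_p"])
})

test_that("confound correction removes gene-size artifacts", {
  withr::with_seed(91, {
    ng <- 400
    len <- runif(ng, 1, 100)
    # null trait where longer genes get systematically better raw scores
    score <- 0.03 * len + rnorm(ng, 0, 0.5)
    tab <- data.frame(gene = sprintf("G%03d", 1:ng), n_snps = round(len / 2),
                      raw_p = 10^(-score), score = score,
                      stringsAsFactors = FALSE)
    conf <- data.frame(gene = tab$gene, length_kb = len,
                       n_snps = tab$n_snps)
    out <- correct_gene_scores(tab, conf)
    expect_lt(abs(cor(out$corrected, len)), abs(cor(tab$score, len)))
    expect_lt(abs(cor(out$corrected, len)), 0.1)
    # orthogonal confounds leave the ranking unchanged
    conf0 <- data.frame(gene = tab$gene, junk = rnorm(ng))
    out0 <- correct_gene_scores(tab, conf0)
    expect_gt(cor(rank(out0$corrected), rank(tab$score)), 0.97)
    # degenerate confounds fall back to raw ranks with a warning
    confc <- data.frame(gene = tab$gene, c1 = 1)
    expect_warning(outc <- correct_gene_scores(tab, confc), "degenerate")
    expect_equal(rank(outc$corrected), rank(tab$score))
  })
})

test_that("the enrichment test counts, nulls and bounds behave", {
  withr::with_seed(92, {
    ng <- 300
    tab <- data.frame(gene = sprintf("G%03d", 1:ng), n_snps = 10L,
                      raw_p = runif(ng), stringsAsFactors = FALSE)
    tab$score <- -log10(tab$raw_p)
    tab$corrected <- tab$score
    tab$percentile <- rank(tab$corrected) / ng
    # candidates = the top-scoring genes: the most extreme possible p
    top <- tab$gene[order(-tab$corrected)][1:40]
    mg <- magenta_test(top, tab, 75, n_perm = 400, seed = 93)
    expect_equal(mg$p, 1 / 401)
    expect_identical(mg$observed, 40L)
    # nominal expected count is (1 - cutoff) x set size
    expect_equal(mg$expected_nominal, 10)
    expect_equal(mg$expected, 10, tolerance = 0.15)
    # a random candidate set is unremarkable
    rand <- sample(tab$gene, 40)
    mg0 <- magenta_test(rand, tab, 75, n_perm = 400, seed = 94)
    expect_gt(mg0$p, 0.01)
    expect_error(magenta_test(c("nope"), tab), "shares no genes")
  })
})

test_that("expression-based selection returns the top fold-change genes", {
  withr::with_seed(95, {
    ex <- simulate_expression(200, 5, enhanced_gene_ids = 1:30,
                              log_fold = 3, seed = 96)
    sel <- select_enhanced_genes(ex, "region01", top_k = 30)
    expect_gte(length(intersect(sel$genes, rownames(ex)[1:30])) / 30, 0.99)
    # top_k = n returns every gene
    expect_length(select_enhanced_genes(ex, 1L, top_k = 1e6)$genes, 200L)
    expect_error(select_enhanced_genes(ex - 100, 1L), "positive")
    expect_error(select_enhanced_genes(ex, "regionXX"), "unknown")
  })
})
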