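# GWAS scan, SNP-to-gene mapping, best-SNP gene scoring with confound
# correction, permutation gene-set enrichment (MAGENTA-style), and
# expression-based candidate-set selection.

#' Per-SNP association scan
#'
#' Ordinary least squares of the phenotype on each SNP dosage plus
#' covariates, with Wald p-values. Implemented by projecting phenotype and
#' dosages on the covariate complement once, so the scan is a single
#' matrix product. Monomorphic SNPs are skipped.
#'
#' @param y phenotype.
#' @param genotypes n x m dosage matrix (missing dosages mean-imputed).
#' @param covariates optional numeric covariate matrix.
#' @param variant_info optional `VariantInfo` to carry through.
#' @return `GwasResults` data.frame: `snp`, `chrom`, `bp`, `a1`, `beta`,
#'   `se`, `p` (NA rows dropped for monomorphic SNPs).
#' @export
gwas_scan <- function(y, genotypes, covariates = NULL, variant_info = NULL) {
  n <- length(y)
  G <- as.matrix(genotypes)
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
  }
  C <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  Q <- qr.Q(qr(C))
  yr <- drop(y - Q %*% crossprod(Q, y))
  QtG <- crossprod(Q, G)
  g2 <- colSums(G^2) - colSums(QtG^2)      # residual sum of squares per SNP
  poly <- g2 > 1e-10 * pmax(colSums(G^2), 1)
  num <- drop(crossprod(G, yr))
  beta <- ifelse(poly, num / g2, NA_real_)
  df <- n - ncol(C) - 1L
  rss <- sum(yr^2) - ifelse(poly, num^2 / g2, 0)
  se <- sqrt(pmax(rss / df, 0) / g2)
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df)
  snp <- colnames(G) %||% sprintf("rs%06d", seq_len(ncol(G)))
  out <- data.frame(snp = snp,
                    chrom = variant_info$chrom %||% "chr1",
                    bp = variant_info$bp %||% seq_len(ncol(G)),
                    a1 = variant_info$a1 %||% "A",
                    beta = beta, se = se, p = p,
                    stringsAsFactors = FALSE)
  out[poly, , drop = FALSE]
}

#' Map SNPs to gene windows
#'
#' A SNP is assigned to every gene whose boundary, extended by `flank_kb`
#' kilobases on each side, contains its position. Gene boundaries are BED
#' conventions (0-based, half-open); SNP positions are 1-based. Overlap is
#' resolved with `IRanges::findOverlaps`, and multi-assignment is allowed.
#'
#' @param variants `VariantInfo` data.frame (`snp`, `chrom`, `bp`).
#' @param gene_bed gene data.frame (`chrom`, `start`, `end`, `gene`).
#' @param flank_kb window flank in kb (default 35; the robustness grid in
#'   the enrichment analysis uses 25/35/50).
#' @return list with `mapping` (data.frame `snp`, `gene`), `n_mapped`,
#'   `n_unmapped`, `unmapped_chroms` (chromosome names present in variants
#'   but absent from the gene table).
#' @export
map_snps_to_genes <- function(variants, gene_bed, flank_kb = 35) {
  flank <- round(flank_kb * 1000)
  shared <- intersect(unique(variants$chrom), unique(gene_bed$chrom))
  missing_chroms <- setdiff(unique(variants$chrom), shared)
  maps <- list()
  for (ch in shared) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    g <- gene_bed[gene_bed$chrom == ch, , drop = FALSE]
    # 1-based window of gene [start0, end0): start0 - flank + 1 .. end0 + flank
    gw <- IRanges::IRanges(start = g$start - flank + 1L, end = g$end + flank)
    sv <- IRanges::IRanges(start = v$bp, width = 1L)
    ov <- IRanges::findOverlaps(sv, gw)
    maps[[ch]] <- data.frame(snp = v$snp[S4Vectors::queryHits(ov)],
                             gene = g$gene[S4Vectors::subjectHits(ov)],
                             stringsAsFactors = FALSE)
  }
  mapping <- if (length(maps)) do.call(rbind, maps) else
    data.frame(snp = character(0), gene = character(0))
  rownames(mapping) <- NULL
  list(mapping = mapping,
       n_mapped = length(unique(mapping$snp)),
       n_unmapped = nrow(variants) - length(unique(mapping$snp)),
       unmapped_chroms = missing_chroms)
}

#' Best-SNP gene scores
#'
#' Each gene's raw score is the minimum association p-value over its mapped
#' SNPs; genes with no mapped SNPs are absent from the table.
#'
#' @param gwas `GwasResults`.
#' @param mapping SNP-to-gene mapping from [map_snps_to_genes()].
#' @return `GeneScoreTable` data.frame: `gene`, `n_snps`, `raw_p` (min p),
#'   `score` (-log10 raw p).
#' @export
gene_scores <- function(gwas, mapping) {
  mp <- mapping$mapping %||% mapping
  if (nrow(mp) == 0L) stopf("empty SNP-to-gene mapping")
  p_of <- gwas$p[match(mp$snp, gwas$snp)]
  ok <- !is.na(p_of)
  raw <- tapply(p_of[ok], mp$gene[ok], min)
  nsnp <- tapply(p_of[ok], mp$gene[ok], length)
  data.frame(gene = names(raw), n_snps = as.integer(nsnp),
             raw_p = as.numeric(raw), score = -log10(as.numeric(raw)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Confound-corrected gene scores
#'
#' Best-SNP scores favor long, SNP-dense genes under the null. The
#' `-log10(min p)` score is regressed (OLS) on the confounds — gene length
#' in kb and mapped SNP count by default — and genes are re-ranked by the
#' residual. Percentile ranks (fraction of genes scoring at or below) are
#' attached for cutoff-based enrichment.
#'
#' @param score_table `GeneScoreTable` from [gene_scores()].
#' @param confounds data.frame with `gene` plus numeric confound columns;
#'   when `NULL`, `n_snps` from the score table is the only confound.
#' @return the score table with `corrected` (residual score) and
#'   `percentile` columns.
#' @export
correct_gene_scores <- function(score_table, confounds = NULL) {
  y <- score_table$score
  X <- if (is.null(confounds)) {
    cbind(n_snps = score_table$n_snps)
  } else {
    as.matrix(confounds[match(score_table$gene, confounds$gene),
                        setdiff(names(confounds), "gene"), drop = FALSE])
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    warnf("degenerate confounds; raw ranks used")
    resid <- y
  } else {
    resid <- stats::lsfit(X, y)$residuals
  }
  score_table$corrected <- resid
  score_table$percentile <- rank(resid, ties.method = "average") /
    nrow(score_table)
  score_table
}

#' MAGENTA-style gene-set enrichment test
#'
#' Counts the candidate genes whose corrected score exceeds the cutoff
#' percentile of all scored genes (e.g. the top 25% at the 75 cutoff) and
#' compares the count with `n_perm` random gene sets of identical size
#' drawn from all scored genes: `p = (1 + #\{null >= observed\}) /
#' (1 + n_perm)`.
#'
#' @param candidate_set character vector of candidate gene ids.
#' @param score_table corrected `GeneScoreTable`.
#' @param cutoff_percentile 75 or 95 (the two conventional cutoffs).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param size_matched if `TRUE`, permuted sets are drawn matched on
#'   mapped-SNP-count deciles.
#' @return `MagentaResult` list: `observed`, `expected` (null-mean count),
#'   `expected_nominal` ((1 - cutoff) x set size), `p`, `set_size`
#'   (candidate genes that are scored), `cutoff_percentile`.
#' @export
magenta_test <- function(candidate_set, score_table,
                         cutoff_percentile = 75, n_perm = 10000, seed = 1,
                         size_matched = FALSE) {
  scored <- score_table$gene
  cand <- intersect(unique(candidate_set), scored)
  if (length(cand) == 0L) stopf("candidate set shares no genes with the scored table")
  thr <- stats::quantile(score_table$corrected, cutoff_percentile / 100,
                         type = 7, names = FALSE)
  above <- score_table$corrected > thr
  names(above) <- scored
  observed <- sum(above[cand])
  k <- length(cand)
  null <- with_seed(seed, {
    if (size_matched) {
      dec <- cut(rank(score_table$n_snps, ties.method = "first"),
                 breaks = 10, labels = FALSE)
      names(dec) <- scored
      pools <- split(seq_along(scored), dec)
      cand_dec <- table(dec[cand])
      vapply(seq_len(n_perm), function(i) {
        idx <- unlist(lapply(names(cand_dec), function(d)
          sample(pools[[d]], cand_dec[[d]])), use.names = FALSE)
        sum(above[idx])
      }, 0L)
    } else {
      vapply(seq_len(n_perm), function(i)
        sum(above[sample.int(length(scored), k)]), 0L)
    }
  })
  list(observed = observed, expected = mean(null),
       expected_nominal = (1 - cutoff_percentile / 100) * k,
       p = (1 + sum(null >= observed)) / (1 + n_perm),
       set_size = k, cutoff_percentile = cutoff_percentile)
}

#' Select region-enhanced genes by expression fold change
#'
#' Fold change per gene = log mean expression in the target region minus
#' log mean expression over all other regions; the `top_k` genes by fold
#' change (descending, ties broken by gene id) form the candidate set.
#'
#' @param expression genes x regions positive matrix.
#' @param target_region column name or index.
#' @param top_k set size (default 1000, capped at the gene count).
#' @return list with `genes` (selected ids), `fold_change` (named, all
#'   genes, sorted), `degenerate` (`TRUE` when the fold changes are all
#'   equal and the selection is an arbitrary tie-break).
#' @export
select_enhanced_genes <- function(expression, target_region, top_k = 1000) {
  if (any(expression <= 0)) stopf("expression must be positive (log fold change)")
  ix <- if (is.character(target_region))
    match(target_region, colnames(expression)) else target_region
  if (is.na(ix) || ix > ncol(expression)) stopf("unknown target region")
  fc <- log(rowMeans(expression[, ix, drop = FALSE])) -
    log(rowMeans(expression[, -ix, drop = FALSE]))
  ord <- order(-fc, rownames(expression))
  degenerate <- diff(range(fc)) < 1e-12
  if (degenerate) warnf("flat fold changes: selection is an arbitrary tie-break")
  top_k <- min(top_k, nrow(expression))
  list(genes = rownames(expression)[ord][seq_len(top_k)],
       fold_change = sort(fc, decreasing = TRUE),
       degenerate = degenerate)
}
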