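# Readers/writers for the interchange formats the pipeline touches:
# PLINK1 binary genotypes (.bed/.bim/.fam, SNP-major), the GCTA GRM binary
# dialect, GMT gene sets, BED gene boundaries, and plain TSV tables.

#' Write genotypes as a PLINK1 binary fileset
#'
#' SNP-major .bed with the v1.00 magic bytes (0x6c 0x1b 0x01); dosages are
#' counts of the A1 allele (2-bit codes: 00 hom A1, 10 het, 11 hom A2,
#' 01 missing).
#'
#' @param prefix file path prefix (writes `prefix.bed/.bim/.fam`).
#' @param genotypes n x m dosage matrix (0/1/2/NA), subjects in rows.
#' @param variant_info data.frame with `snp`, `chrom`, `bp`, `a1`, `a2`.
#' @param subjects subject ids (defaults to rownames).
#' @return invisibly, the prefix.
#' @export
write_plink <- function(prefix, genotypes, variant_info, subjects = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  subjects <- subjects %||% rownames(genotypes) %||% paste0("s", seq_len(n))
  fam <- data.frame(fid = subjects, iid = subjects, pat = 0L, mat = 0L,
                    sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  chrom_num <- sub("^chr", "", variant_info$chrom)
  bim <- data.frame(chrom = chrom_num, snp = variant_info$snp, cm = 0,
                    bp = variant_info$bp, a1 = variant_info$a1,
                    a2 = variant_info$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # 2-bit code per dosage of A1: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, m)
  code[genotypes == 1L] <- 2L
  code[genotypes == 2L] <- 0L
  code[is.na(genotypes)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4L - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  shifts <- rep(c(1L, 4L, 16L, 64L), bytes_per_snp)
  packed <- code * shifts
  dim(packed) <- c(4L, bytes_per_snp * m)
  bytes <- as.raw(colSums(packed))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read a PLINK1 binary fileset
#'
#' @param prefix path prefix of `prefix.bed/.bim/.fam`.
#' @return list with `genotypes` (n x m A1-dosage matrix with subject
#'   rownames and SNP colnames), `variant_info`, `fam`.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"),
                           colClasses = c("character", "character", rep(NA, 4)))
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chrom", "snp", "cm", "bp", "a1",
                                         "a2"),
                           colClasses = c("character", "character", NA, NA,
                                          "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stopf("not a SNP-major PLINK1 .bed file")
  raw <- readBin(con, "raw", bytes_per_snp * m)
  v <- as.integer(raw)
  codes <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  dim(codes) <- c(4L * bytes_per_snp, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  rownames(dos) <- fam$iid
  colnames(dos) <- bim$snp
  vi <- data.frame(snp = bim$snp, chrom = bim$chrom, bp = bim$bp,
                   a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE)
  list(genotypes = dos, variant_info = vi, fam = fam)
}

#' Write a GRM in the GCTA binary dialect
#'
#' `prefix.grm.bin`: float32 lower triangle (including diagonal), row-wise;
#' `prefix.grm.id`: two-column id table; `prefix.grm.N.bin`: float32 SNP
#' counts per pair.
#'
#' @param prefix path prefix.
#' @param grm `GRM` object from [compute_grm()] (or a plain symmetric
#'   matrix).
#' @param n_snps SNPs per pair (scalar or matrix; default from the object).
#' @return invisibly, the prefix.
#' @export
write_grm <- function(prefix, grm, n_snps = NULL) {
  A <- if (is.list(grm)) grm$A else grm
  ids <- if (is.list(grm)) grm$subjects else rownames(A) %||%
    paste0("s", seq_len(nrow(A)))
  n_snps <- n_snps %||% (if (is.list(grm)) grm$n_snps else 0L)
  n <- nrow(A)
  lt <- A[row(A) >= col(A)]
  # row-wise lower triangle: pair (i, j <= i) ordered by i then j
  idx <- which(row(A) >= col(A), arr.ind = TRUE)
  o <- order(idx[, 1L], idx[, 2L])
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt[o]), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_snps), length(lt)), con, size = 4L)
  close(con)
  utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA-dialect binary GRM
#'
#' @param prefix path prefix of `.grm.bin/.grm.id` files.
#' @return `GRM` list with `A`, `subjects`, `n_snps`.
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           colClasses = "character")
  n <- nrow(ids)
  nt <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  vals <- readBin(con, "numeric", nt, size = 4L)
  close(con)
  A <- matrix(0, n, n)
  A[row(A) >= col(A)][order(which(row(A) >= col(A), arr.ind = TRUE)[, 1L],
                            which(row(A) >= col(A), arr.ind = TRUE)[, 2L])] <- vals
  A <- A + t(A) - diag(diag(A))
  rownames(A) <- colnames(A) <- ids[[2L]]
  nfile <- paste0(prefix, ".grm.N.bin")
  n_snps <- if (file.exists(nfile)) {
    con <- file(nfile, "rb")
    x <- readBin(con, "numeric", 1L, size = 4L)
    close(con)
    x
  } else NA_real_
  list(A = A, subjects = ids[[2L]], n_snps = n_snps)
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, tab-separated member genes.
#'
#' @param path output path.
#' @param gene_sets named list of character vectors.
#' @param descriptions optional descriptions (defaults to the names).
#' @export
write_gmt <- function(path, gene_sets, descriptions = NULL) {
  descriptions <- descriptions %||% names(gene_sets)
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "", USE.NAMES = FALSE)
  out
}

#' Write gene boundaries as BED (0-based, half-open)
#'
#' @param path output path.
#' @param genes data.frame with `chrom`, `start`, `end`, `gene`.
#' @export
write_bed_genes <- function(path, genes) {
  utils::write.table(genes[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene-boundary BED file
#'
#' @param path BED path (first four columns chrom/start/end/name).
#' @return data.frame with `chrom`, `start`, `end`, `gene`.
#' @export
read_bed_genes <- function(path) {
  g <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)[, 1:4]
  names(g) <- c("chrom", "start", "end", "gene")
  g
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a cohort's blocks to a directory of flat files
#'
#' Trials, scores and covariates as TSV; edges as TSV (subjects x edges);
#' genotypes as a PLINK fileset; gene boundaries as BED; gene sets as GMT;
#' expression as TSV; truth (scalar planted parameters) as JSON.
#'
#' @param cohort `CohortDataset` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$trials, file.path(dir, "trials.tsv"))
  write_tsv(cohort$scores, file.path(dir, "scores.tsv"))
  write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_tsv(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  edges <- data.frame(subject = rownames(cohort$edges), cohort$edges,
                      check.names = FALSE)
  write_tsv(edges, file.path(dir, "edges.tsv"))
  write_plink(file.path(dir, "genotypes"), cohort$genotypes,
              cohort$variant_info)
  write_bed_genes(file.path(dir, "genes.bed"), cohort$genes)
  write_gmt(file.path(dir, "gene_sets.gmt"), cohort$gene_sets)
  expr <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                     check.names = FALSE)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  tr <- cohort$truth
  truth_json <- list(target_h2 = as.list(tr$target_h2),
                     target_rg = tr$target_rg, pvm = tr$pvm, b = tr$b,
                     informative_edges = tr$informative_edges,
                     enhanced_genes = tr$enhanced_genes)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
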