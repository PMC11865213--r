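#' Write / read genotypes as a dosage TSV
#'
#' One row per SNP: `snp_id`, `chrom`, `pos`, `allele1`, `allele2`,
#' `qc_violation`, then one column per sample with dosages 0/1/2 or `NA`.
#'
#' @param genotypes `genotype_matrix`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$map, as.data.frame(t(genotypes$dosage)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  map_cols <- c("snp_id", "chrom", "pos", "allele1", "allele2", "qc_violation")
  map_cols <- intersect(map_cols, names(df))
  map <- df[, map_cols, drop = FALSE]
  map$chrom <- as.character(map$chrom)
  dos <- t(as.matrix(df[, setdiff(names(df), map_cols), drop = FALSE]))
  colnames(dos) <- map$snp_id
  genotype_matrix(dos, map)
}

#' Write genotypes as a minimal VCF (v4.2, unphased GT)
#'
#' Dosages are emitted as `0/0`, `0/1`, `1/1` or `./.` in a GT-only FORMAT
#' column; ALT is the second allele, whose dosage count the matrix stores.
#'
#' @param genotypes `genotype_matrix`.
#' @param path output file (plain text).
#' @return invisibly, the path.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  map <- genotypes$map
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  D <- t(genotypes$dosage)                  # SNP x sample
  GT <- matrix("./.", nrow(D), ncol(D))
  for (v in c("0", "1", "2"))
    GT[!is.na(D) & D == as.numeric(v)] <- gt_code[[v]]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes$dosage)),
                    collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$snp_id, map$allele1, map$allele2,
                ".", ".", ".", "GT",
                apply(GT, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses the GT field of a diploid VCF into 0/1/2 dosages of the ALT
#' allele (missing genotypes become `NA`).
#'
#' @param path VCF file.
#' @return `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt_clean <- gsub("\\|", "/", gt)
  dos[gt_clean == "0/0"] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean == "1/1"] <- 2L
  map <- data.frame(snp_id = unname(fix[, "ID"]),
                    chrom = unname(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]),
                    allele1 = unname(fix[, "REF"]),
                    allele2 = unname(fix[, "ALT"]),
                    stringsAsFactors = FALSE)
  genotype_matrix(t(dos), map)
}

#' Write / read gene annotation as GFF3
#'
#' Gene intervals (1-based, inclusive) round-trip through GFF3 via
#' `rtracklayer`.
#'
#' @param annotation `annotation_index` data.frame (`gene_id`, `gene_name`,
#'   `chrom`, `start`, `end`).
#' @param path output `.gff3` file.
#' @return invisibly, the path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    type = "gene", ID = annotation$gene_id,
    Name = if ("gene_name" %in% names(annotation)) annotation$gene_name
           else annotation$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ann <- data.frame(gene_id = gr$ID,
                    gene_name = if (!is.null(gr$Name)) gr$Name else gr$ID,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  class(ann) <- c("annotation_index", "data.frame")
  ann
}

#' Write an expression matrix as TSV with a gene-length column
#'
#' @param counts gene x sample count matrix.
#' @param lengths per-gene lengths (bp).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_expression_tsv <- function(counts, lengths, path) {
  df <- data.frame(gene_id = rownames(counts), length = lengths,
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "length")),
                         drop = FALSE])
  rownames(counts) <- df$gene_id
  list(counts = counts, lengths = setNames(df$length, df$gene_id))
}
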