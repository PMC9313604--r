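#' Genotype matrix container
#'
#' Lightweight container for a samples x loci matrix of biallelic SNP codes
#' (0 = major homozygote, 1 = heterozygote, 2 = minor homozygote, NA = missing)
#' together with locus metadata.
#'
#' @param codes integer matrix, samples in rows, loci in columns; entries in
#'   \{0, 1, 2, NA\}. Row names are sample ids.
#' @param loci data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}; one row per column of \code{codes}. Positions must
#'   be strictly increasing within each chromosome.
#' @param pool optional character vector of pool labels per sample (e.g.
#'   "pool1"/"pool2" for temperate/tropical-style groups).
#' @return An object of class \code{geno}.
#' @export
geno_matrix <- function(codes, loci, pool = NULL) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("S%03d", seq_len(nrow(codes)))
  }
  stopifnot(is.data.frame(loci), nrow(loci) == ncol(codes),
            all(c("chrom", "pos") %in% names(loci)))
  if (is.null(loci$ref)) loci$ref <- "A"
  if (is.null(loci$alt)) loci$alt <- "T"
  bad <- setdiff(unique(as.vector(codes)), c(0L, 1L, 2L, NA))
  if (length(bad)) stop("genotype codes must be 0/1/2/NA, found: ",
                        paste(bad, collapse = ", "))
  for (ch in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(colnames(codes))) {
    colnames(codes) <- paste0(loci$chrom, "_", loci$pos)
  }
  if (!is.null(pool)) {
    stopifnot(length(pool) == nrow(codes))
    pool <- as.character(pool)
  }
  structure(list(codes = codes, loci = as.data.frame(loci), pool = pool),
            class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("geno: ", nrow(x$codes), " samples x ", ncol(x$codes), " loci on ",
      length(unique(x$loci$chrom)), " chromosome(s)\n", sep = "")
  if (!is.null(x$pool)) {
    tb <- table(x$pool)
    cat("pools:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  miss <- mean(is.na(x$codes))
  cat(sprintf("missing: %.2f%%; mean MAF: %.3f\n", 100 * miss,
              mean(locus_maf(x), na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$codes)

#' Subset a geno object by samples and/or loci
#' @param x a \code{geno} object
#' @param samples sample indices or ids (optional)
#' @param loci locus indices (optional)
#' @return a \code{geno} object
#' @export
geno_subset <- function(x, samples = NULL, loci = NULL) {
  codes <- x$codes
  pool <- x$pool
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(codes))
    if (anyNA(samples)) stop("unknown sample id(s)")
    codes <- codes[samples, , drop = FALSE]
    if (!is.null(pool)) pool <- pool[samples]
  }
  tab <- x$loci
  if (!is.null(loci)) {
    codes <- codes[, loci, drop = FALSE]
    tab <- tab[loci, , drop = FALSE]
    rownames(tab) <- NULL
  }
  geno_matrix(codes, tab, pool)
}

#' Per-locus minor allele frequency
#'
#' MAF computed on non-missing calls; by container convention code 2 counts the
#' minor allele, so MAF = mean(code)/2 capped at 0.5 only when orientation is
#' respected. Values > 0.5 can occur on raw external input before
#' \code{\link{orient_minor}}.
#'
#' @param g a \code{geno} object
#' @return numeric vector of alt/minor allele frequencies per locus
#' @export
locus_maf <- function(g) {
  colMeans(g$codes, na.rm = TRUE) / 2
}

#' Re-orient codes so that 2 is the minor homozygote
#'
#' Loci where the coded allele frequency exceeds 0.5 are flipped (0 <-> 2,
#' ref/alt swapped). Ties (frequency exactly 0.5) are left oriented toward the
#' alt allele.
#'
#' @param g a \code{geno} object
#' @return a \code{geno} object with alt-allele frequency <= 0.5 at every locus
#' @export
orient_minor <- function(g) {
  f <- colMeans(g$codes, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) {
    g$codes[, flip] <- 2L - g$codes[, flip]
    r <- g$loci$ref[flip]
    g$loci$ref[flip] <- g$loci$alt[flip]
    g$loci$alt[flip] <- r
  }
  g
}

#' Read genotypes from VCF or CSV
#'
#' VCF input uses the GT field of biallelic SNP records; multi-allelic sites are
#' skipped with a warning. CSV input is a sample x locus table of codes 0/1/2
#' with a header row of locus ids \code{chrom_pos} and sample ids in the first
#' column. After reading, codes are oriented so 2 is the minor homozygote
#' (ties kept toward the alt allele).
#'
#' @param path file path
#' @param format "vcf" or "csv"
#' @return a \code{geno} object
#' @export
read_genotypes <- function(path, format = c("vcf", "csv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt) | nchar(fix[, "REF"]) != 1L | nchar(alt) != 1L
    if (any(multi)) {
      warning(sum(multi), " multi-allelic or non-SNP site(s) skipped")
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
    clean <- gsub("\\|", "/", gt)
    code[clean %in% c("0/0")] <- 0L
    code[clean %in% c("0/1", "1/0")] <- 1L
    code[clean %in% c("1/1")] <- 2L
    bad <- !is.na(clean) & !(clean %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(bad)) stop("malformed GT value(s), e.g. ", clean[which(bad)[1]])
    codes <- t(code)
    rownames(codes) <- colnames(gt)
    loci <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       stringsAsFactors = FALSE)
    g <- geno_matrix(codes, loci)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    codes <- as.matrix(df[, -1, drop = FALSE])
    mode(codes) <- "integer"
    rownames(codes) <- df[[1]]
    ids <- colnames(codes)
    parts <- regmatches(ids, regexpr("_[0-9]+$", ids))
    chrom <- sub("_[0-9]+$", "", ids)
    pos <- as.integer(sub("^_", "", parts))
    loci <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                       stringsAsFactors = FALSE)
    g <- geno_matrix(codes, loci)
  }
  orient_minor(g)
}

#' Write genotypes to VCF or CSV
#'
#' Inbred parents are written as 0/0 or 1/1; heterozygous (hybrid) calls as
#' 0/1; missing as ./. . VCF output is gzip-compressed (the conventional
#' on-disk form); pass a path ending in .vcf.gz.
#'
#' @param g a \code{geno} object
#' @param path output path
#' @param format "vcf" or "csv"
#' @return the path, invisibly
#' @importFrom methods new
#' @export
write_genotypes <- function(g, path, format = c("vcf", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(sample = rownames(g$codes), g$codes, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = ncol(g$codes), ncol = nrow(g$codes))
  for (k in 0:2) gt[t(g$codes) == k] <- gt_map[[as.character(k)]]
  colnames(gt) <- rownames(g$codes)
  fix <- cbind(CHROM = as.character(g$loci$chrom),
               POS = as.character(g$loci$pos),
               ID = colnames(g$codes),
               REF = g$loci$ref, ALT = g$loci$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  v <- new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
           fix = fix,
           gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
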