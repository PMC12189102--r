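#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), types every biallelic record as
#' SNP/INS/DEL by REF/ALT length comparison (or `SVTYPE` for symbolic
#' alleles), honours `SVLEN`/`END` when present, and converts genotypes to
#' ALT-allele dosages with missing calls preserved as `NA`. VCF 1-based
#' positions are converted to the internal 0-based half-open convention
#' once, here.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param layout Optional [genome_layout()]; records on chromosomes absent
#'   from the layout are an error.
#' @param samples Optional character vector restricting the sample columns.
#' @param multiallelic `"error"` (default) or `"skip"`: what to do with
#'   records whose ALT holds more than one allele.
#' @param info_keys Numeric INFO keys to extract as columns when present.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, layout = NULL, samples = NULL,
                     multiallelic = c("error", "skip"),
                     info_keys = c("QD", "FS", "SOR", "MQ", "MQRankSum",
                                   "ReadPosRankSum")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0("var", which(is.na(id) | id == "."))

  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error") {
      stop(sum(multi), " multiallelic record(s); only biallelic variants are supported ",
           "(use multiallelic = \"skip\" to drop them)")
    }
    keep0 <- !multi
  } else keep0 <- rep(TRUE, length(pos))

  # sortedness check (per chromosome, in file order)
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]
    if (is.unsorted(p)) stop("VCF not sorted by position on ", chr)
  }
  if (!is.null(layout)) {
    unknown <- setdiff(unique(chrom), layout$chrom)
    if (length(unknown) > 0) {
      stop("VCF chromosome(s) not in genome layout: ", paste(unknown, collapse = ", "))
    }
  }

  get_info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = key)))
  }
  svtype <- vcfR::extract.info(vcf, element = "SVTYPE")
  svlen <- get_info_num("SVLEN")
  endinfo <- get_info_num("END")

  symbolic <- startsWith(alt, "<")
  vtype <- character(length(pos))
  len <- numeric(length(pos))
  reflen <- nchar(ref); altlen <- nchar(alt)
  vtype[symbolic] <- toupper(svtype[symbolic])
  plain <- !symbolic
  vtype[plain & altlen > reflen] <- "INS"
  vtype[plain & altlen < reflen] <- "DEL"
  vtype[plain & altlen == reflen & reflen == 1] <- "SNP"
  if (any(vtype == "" | !(vtype %in% c("SNP", "INS", "DEL")))) {
    bad <- which(!(vtype %in% c("SNP", "INS", "DEL")))
    stop("cannot type record(s) as SNP/INS/DEL (e.g. MNP or unknown SVTYPE) at row ", bad[1])
  }
  len[plain] <- abs(altlen - reflen)[plain]
  len[vtype == "SNP"] <- 1
  len[symbolic] <- abs(svlen[symbolic])
  use_end <- symbolic & vtype == "DEL" & !is.na(endinfo) & is.na(svlen)
  len[use_end] <- endinfo[use_end] - pos[use_end]
  if (anyNA(len[symbolic])) stop("symbolic allele without SVLEN or END")

  # 0-based half-open spans; POS anchors the base before an indel event
  start <- ifelse(vtype == "SNP", pos - 1, pos)
  end <- ifelse(vtype == "DEL", pos + len,
                ifelse(vtype == "SNP", pos, pos))
  if (!is.null(layout)) {
    if (any(end > chrom_length(layout, chrom))) {
      stop("variant span exceeds chromosome length")
    }
  }

  variants <- data.frame(variant_id = id, chrom = chrom, pos = pos,
                         start = start, end = end, vtype = vtype,
                         length = len, qual = qual, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  for (key in info_keys) variants[[key]] <- get_info_num(key)

  geno <- NULL
  if (ncol(vcf@gt) > 1) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    geno <- gt_to_dosage(gt)
    if (!is.null(samples)) {
      miss <- setdiff(samples, colnames(geno))
      if (length(miss) > 0) stop("sample(s) not in VCF: ", paste(miss, collapse = ", "))
      geno <- geno[, samples, drop = FALSE]
    }
  }
  vt <- variant_table(variants[keep0, , drop = FALSE],
                      if (is.null(geno)) NULL else geno[keep0, , drop = FALSE])
  vt
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  core <- sub(":.*", "", gt)
  d[core %in% c("0/0", "0|0")] <- 0L
  d[core %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[core %in% c("1/1", "1|1")] <- 2L
  d
}

#' Write a variant table as VCF 4.2
#'
#' Emits a minimal well-formed VCF: contig lines from the layout, the INFO
#' annotations present as columns, GT-only genotypes. Used chiefly to
#' materialise synthetic cohorts so that the production reader is exercised.
#'
#' @param vt A [variant_table()] whose `variants` carry `ref`/`alt` columns.
#' @param path Output path.
#' @param layout A [genome_layout()] for the contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path, layout = NULL) {
  v <- vt$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(layout)) {
    writeLines(sprintf("##contig=<ID=%s,length=%s>", layout$chrom,
                       format_bp(layout$length)), con)
  }
  num_keys <- intersect(c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum"),
                        names(v))
  for (k in num_keys) {
    writeLines(sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k), con)
  }
  writeLines(c("##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
           vt$samples)
  writeLines(paste(hdr, collapse = "\t"), con)

  info <- vapply(seq_len(nrow(v)), function(i) {
    parts <- character()
    symbolic <- startsWith(v$alt[i], "<")
    if (symbolic) {
      sl <- if (v$vtype[i] == "DEL") -v$length[i] else v$length[i]
      parts <- c(parts, paste0("SVTYPE=", v$vtype[i]), paste0("SVLEN=", sl))
      if (v$vtype[i] == "DEL") parts <- c(parts, paste0("END=", format_bp(v$pos[i] + v$length[i])))
    }
    for (k in num_keys) {
      if (!is.na(v[[k]][i])) parts <- c(parts, paste0(k, "=", v[[k]][i]))
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, "")

  gts <- if (length(vt$samples) > 0) {
    g <- matrix(".\t", nrow = nrow(v), ncol = 0)
    m <- vt$geno
    txt <- matrix("./.", nrow = nrow(m), ncol = ncol(m))
    txt[!is.na(m) & m == 0L] <- "0/0"
    txt[!is.na(m) & m == 1L] <- "0/1"
    txt[!is.na(m) & m == 2L] <- "1/1"
    apply(txt, 1, paste, collapse = "\t")
  } else NULL

  body <- paste(v$chrom, format_bp(v$pos), v$variant_id, v$ref, v$alt,
                ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE)),
                "PASS", info, sep = "\t")
  if (!is.null(gts)) body <- paste(body, "GT", gts, sep = "\t")
  writeLines(body, con)
  invisible(path)
}
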