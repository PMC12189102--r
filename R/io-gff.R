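#' Read GFF3 gene models
#'
#' Loads gene/transcript/exon/CDS/UTR features from a GFF3 file (via
#' \pkg{rtracklayer}) and resolves the parent hierarchy into a
#' `gene_model_set`: per-feature interval tables in 0-based half-open
#' coordinates, with introns derived as the gaps between consecutive exons
#' of each transcript. Transcripts of type `mRNA` are treated as coding;
#' any other transcript type (`ncRNA`, `lnc_RNA`, `transcript`, ...) as
#' non-coding.
#'
#' An exon whose `Parent` cannot be resolved is assigned to a synthetic
#' singleton transcript with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_model_set`: list with data frames `genes`, `transcripts`,
#'   `exons`, `cds`, `utr5`, `utr3`, `introns` (all 0-based half-open).
#' @export
read_gff_genes <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$ID <- if (is.null(g[["ID"]])) rep(NA_character_, nrow(g)) else as.character(g$ID)
  g$parent <- if (is.null(g[["Parent"]])) {
    rep(NA_character_, nrow(g))
  } else {
    vapply(g$Parent, function(p) if (length(p) == 0) NA_character_ else p[[1]], "")
  }
  g$start0 <- g$start - 1  # GFF3 is 1-based inclusive
  g$end0 <- g$end
  type <- as.character(g$type)

  tx_types <- c("mRNA", "ncRNA", "lnc_RNA", "transcript", "tRNA", "rRNA",
                "snoRNA", "snRNA", "miRNA", "pseudogenic_transcript")
  is_gene <- type %in% c("gene", "ncRNA_gene", "pseudogene")
  is_tx <- type %in% tx_types
  genes <- data.frame(gene_id = g$ID[is_gene], chrom = as.character(g$seqid[is_gene]),
                      start = g$start0[is_gene], end = g$end0[is_gene],
                      strand = as.character(g$strand[is_gene]),
                      stringsAsFactors = FALSE)
  tx <- data.frame(tx_id = g$ID[is_tx], gene_id = g$parent[is_tx],
                   chrom = as.character(g$seqid[is_tx]),
                   start = g$start0[is_tx], end = g$end0[is_tx],
                   strand = as.character(g$strand[is_tx]),
                   coding = type[is_tx] == "mRNA",
                   stringsAsFactors = FALSE)

  sub_tab <- function(ty) {
    i <- type %in% ty
    data.frame(tx_id = g$parent[i], chrom = as.character(g$seqid[i]),
               start = g$start0[i], end = g$end0[i], stringsAsFactors = FALSE)
  }
  exons <- sub_tab("exon")
  cds <- sub_tab("CDS")
  utr5 <- sub_tab("five_prime_UTR")
  utr3 <- sub_tab("three_prime_UTR")

  # orphan exons -> synthetic singleton transcripts
  orphan <- !(exons$tx_id %in% tx$tx_id)
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) without resolvable parent; assigned to synthetic transcripts")
    oid <- paste0("orphan_tx_", seq_len(sum(orphan)))
    tx <- rbind(tx, data.frame(tx_id = oid, gene_id = oid,
                               chrom = exons$chrom[orphan],
                               start = exons$start[orphan], end = exons$end[orphan],
                               strand = "+", coding = FALSE))
    exons$tx_id[orphan] <- oid
  }

  # genes that appear only as transcript parents (no gene feature row)
  missing_genes <- setdiff(tx$gene_id, genes$gene_id)
  if (length(missing_genes) > 0) {
    add <- do.call(rbind, lapply(missing_genes, function(gid) {
      d <- tx[tx$gene_id == gid, ]
      data.frame(gene_id = gid, chrom = d$chrom[1], start = min(d$start),
                 end = max(d$end), strand = d$strand[1])
    }))
    genes <- rbind(genes, add)
  }

  introns <- derive_introns(exons)
  structure(list(genes = genes, transcripts = tx, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3, introns = introns),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d genes, %d transcripts (%d coding), %d exons\n",
              nrow(x$genes), nrow(x$transcripts), sum(x$transcripts$coding),
              nrow(x$exons)))
  invisible(x)
}

## introns = gaps between consecutive exons of one transcript (half-open)
derive_introns <- function(exons) {
  if (nrow(exons) == 0) {
    return(data.frame(tx_id = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  }
  out <- lapply(split(exons, exons$tx_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    o <- order(d$start)
    s <- d$end[o][-nrow(d)]
    e <- d$start[o][-1]
    keep <- e > s
    if (!any(keep)) return(NULL)
    data.frame(tx_id = d$tx_id[1], chrom = d$chrom[1],
               start = s[keep], end = e[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(tx_id = character(), chrom = character(),
                               start = numeric(), end = numeric())
  else `rownames<-`(out, NULL)
}

#' Write a gene model set as GFF3
#'
#' Emits gene, mRNA/ncRNA, exon, CDS and UTR rows with ID/Parent linkage,
#' converting back to GFF3 1-based inclusive coordinates. Counterpart of
#' [read_gff_genes()] for synthetic cohorts.
#'
#' @param gm A `gene_model_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  row <- function(chrom, type, s, e, strand, attr) {
    sprintf("%s\tsvscape\t%s\t%s\t%s\t.\t%s\t.\t%s",
            chrom, type, format_bp(s + 1), format_bp(e), strand, attr)
  }
  lines <- character()
  for (i in seq_len(nrow(gm$genes))) {
    gn <- gm$genes[i, ]
    lines <- c(lines, row(gn$chrom, "gene", gn$start, gn$end, gn$strand,
                          paste0("ID=", gn$gene_id)))
    txs <- gm$transcripts[gm$transcripts$gene_id == gn$gene_id, ]
    for (j in seq_len(nrow(txs))) {
      t1 <- txs[j, ]
      ttype <- if (t1$coding) "mRNA" else "ncRNA"
      lines <- c(lines, row(t1$chrom, ttype, t1$start, t1$end, t1$strand,
                            paste0("ID=", t1$tx_id, ";Parent=", gn$gene_id)))
      for (tab in c("exons", "cds", "utr5", "utr3")) {
        d <- gm[[tab]][gm[[tab]]$tx_id == t1$tx_id, ]
        if (nrow(d) == 0) next
        ftype <- c(exons = "exon", cds = "CDS", utr5 = "five_prime_UTR",
                   utr3 = "three_prime_UTR")[[tab]]
        for (k in seq_len(nrow(d))) {
          lines <- c(lines, row(d$chrom[k], ftype, d$start[k], d$end[k],
                                t1$strand, paste0("Parent=", t1$tx_id)))
        }
      }
    }
  }
  writeLines(lines, con)
  invisible(path)
}
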