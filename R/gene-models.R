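#' Construct a gene model
#'
#' A gene model is one annotated transcription unit: its genomic interval,
#' strand, biotype, and (for coding genes) the 5'UTR/CDS/3'UTR sub-intervals.
#' All internal coordinates are 0-based half-open; GFF3 input/output keeps its
#' native 1-based closed convention (see [read_gene_models()]).
#'
#' @param gene_id Gene identifier.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 0-based half-open genomic interval of the transcription
#'   unit (`start < end`).
#' @param biotype `"coding"` or `"ncRNA"`. Coding genes must carry the three
#'   sub-intervals; ncRNA genes must not.
#' @param utr5,cds,utr3 Optional length-2 numeric vectors `c(start, end)`,
#'   0-based half-open, nested within `[start, end)`.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       biotype = c("coding", "ncRNA"),
                       utr5 = NULL, cds = NULL, utr3 = NULL) {
  biotype <- match.arg(biotype)
  g <- structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, start = as.integer(start), end = as.integer(end),
         biotype = biotype, utr5 = utr5, cds = cds, utr3 = utr3),
    class = "gene_model")
  validate_gene_model(g)
}

validate_gene_model <- function(g) {
  if (!g$strand %in% c("+", "-"))
    stop("gene ", g$gene_id, ": strand must be '+' or '-'")
  if (!(g$start < g$end))
    stop("gene ", g$gene_id, ": start must be < end")
  subs <- list(utr5 = g$utr5, cds = g$cds, utr3 = g$utr3)
  subs <- subs[!vapply(subs, is.null, logical(1))]
  if (g$biotype == "ncRNA" && length(subs) > 0L)
    stop("gene ", g$gene_id, ": ncRNA genes cannot carry UTR/CDS sub-intervals")
  if (g$biotype == "coding" && length(subs) < 3L)
    stop("gene ", g$gene_id, ": coding genes need utr5, cds and utr3")
  for (nm in names(subs)) {
    iv <- subs[[nm]]
    if (length(iv) != 2L || iv[1] >= iv[2])
      stop("gene ", g$gene_id, ": malformed ", nm, " interval")
    if (iv[1] < g$start || iv[2] > g$end)
      stop("gene ", g$gene_id, ": ", nm, " outside gene interval")
  }
  if (length(subs) == 3L) {
    # transcription order 5'UTR -> CDS -> 3'UTR; genomic order mirrors on '-'
    ord <- if (g$strand == "+") list(g$utr5, g$cds, g$utr3)
           else list(g$utr3, g$cds, g$utr5)
    for (i in 1:2) {
      if (ord[[i]][2] > ord[[i + 1]][1])
        stop("gene ", g$gene_id,
             ": UTR/CDS sub-intervals overlap or are out of order")
    }
  }
  g
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) [%s]\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, x$biotype))
  invisible(x)
}

#' Transcription start position of a gene model
#'
#' @param g A `gene_model`.
#' @return 0-based position of the first transcribed base.
#' @keywords internal
gene_tss <- function(g) if (g$strand == "+") g$start else g$end - 1L

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS/UTR rows into one [gene_model()] per gene.
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. Genes without CDS rows become biotype `"ncRNA"`.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects (names are gene ids).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop("malformed GFF3 line ", bad, " in ", path,
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (length(genes) == 0L) stop("no gene rows in ", path)
  gid <- gff3_gene_id(genes)

  child_gene <- gff3_owner_gene(gr, gid, genes)
  out <- vector("list", length(genes))
  names(out) <- gid
  for (i in seq_along(genes)) {
    g <- genes[i]
    id <- gid[i]
    kids <- gr[!is.na(child_gene) & child_gene == id]
    ktyp <- as.character(kids$type)
    has_cds <- any(ktyp == "CDS")
    iv <- function(t) {
      k <- kids[ktyp == t]
      if (length(k) == 0L) return(NULL)
      c(min(GenomicRanges::start(k)) - 1L, max(GenomicRanges::end(k)))
    }
    out[[i]] <- gene_model(
      gene_id = id, chrom = as.character(GenomicRanges::seqnames(g)),
      strand = as.character(GenomicRanges::strand(g)),
      start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g),
      biotype = if (has_cds) "coding" else "ncRNA",
      utr5 = if (has_cds) iv("five_prime_UTR") else NULL,
      cds = if (has_cds) iv("CDS") else NULL,
      utr3 = if (has_cds) iv("three_prime_UTR") else NULL)
  }
  out
}

gff3_gene_id <- function(genes) {
  id <- genes$ID
  if (is.null(id) || anyNA(id)) stop("GFF3 gene rows must carry an ID attribute")
  as.character(id)
}

# map every feature row to the gene that owns it (via ID/Parent chains)
gff3_owner_gene <- function(gr, gene_ids, genes) {
  id <- as.character(gr$ID)
  parent <- gr$Parent
  parent <- vapply(as.list(parent), function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[1]), character(1))
  owner <- rep(NA_character_, length(gr))
  owner[parent %in% gene_ids] <- parent[parent %in% gene_ids]
  # second level: exon/CDS/UTR children of mRNAs
  mrna <- !is.na(id) & !is.na(owner)
  lut <- stats::setNames(owner[mrna], id[mrna])
  unresolved <- is.na(owner) & !is.na(parent)
  owner[unresolved] <- lut[parent[unresolved]]
  owner
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gene_models()]: internal 0-based half-open intervals are
#' converted back to GFF3 1-based closed coordinates. Coding genes emit
#' gene/mRNA/five_prime_UTR/CDS/three_prime_UTR rows; ncRNA genes emit
#' gene/exon rows.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  rows <- character(0)
  fmt <- function(chrom, type, s0, e0, strand, attrs)
    sprintf("%s\tapashift\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s0 + 1L, e0, strand, attrs)
  for (g in genes) {
    rows <- c(rows, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                        sprintf("ID=%s", g$gene_id)))
    if (g$biotype == "coding") {
      tid <- paste0(g$gene_id, ".1")
      rows <- c(rows,
        fmt(g$chrom, "mRNA", g$start, g$end, g$strand,
            sprintf("ID=%s;Parent=%s", tid, g$gene_id)),
        fmt(g$chrom, "exon", g$start, g$end, g$strand,
            sprintf("ID=%s.e1;Parent=%s", tid, tid)),
        fmt(g$chrom, "five_prime_UTR", g$utr5[1], g$utr5[2], g$strand,
            sprintf("ID=%s.u5;Parent=%s", tid, tid)),
        fmt(g$chrom, "CDS", g$cds[1], g$cds[2], g$strand,
            sprintf("ID=%s.c;Parent=%s", tid, tid)),
        fmt(g$chrom, "three_prime_UTR", g$utr3[1], g$utr3[2], g$strand,
            sprintf("ID=%s.u3;Parent=%s", tid, tid)))
    } else {
      tid <- paste0(g$gene_id, ".1")
      rows <- c(rows,
        fmt(g$chrom, "ncRNA", g$start, g$end, g$strand,
            sprintf("ID=%s;Parent=%s", tid, g$gene_id)),
        fmt(g$chrom, "exon", g$start, g$end, g$strand,
            sprintf("ID=%s.e1;Parent=%s", tid, tid)))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
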