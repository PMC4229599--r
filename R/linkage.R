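#' Read gene models from a GFF3 file
#'
#' Imports `type = "gene"` features via \pkg{rtracklayer} and returns the
#' coordinate table used by the linkage analysis (1-based inclusive
#' coordinates, GFF3 dialect). The `ID` attribute (falling back to
#' `locus_tag` or `Name`) supplies the gene id.
#'
#' @param path Path to a GFF3 file.
#' @return `data.frame(gene_id, contig, start, end, strand)`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) stop("no 'gene' features in ", path)
  md <- S4Vectors::mcols(gr)
  id <- if (!is.null(md$ID)) md$ID
        else if (!is.null(md$locus_tag)) md$locus_tag
        else md$Name
  if (is.null(id)) stop("gene features carry no ID/locus_tag/Name attribute")
  data.frame(
    gene_id = as.character(id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write gene models as GFF3
#'
#' @param genes `data.frame(gene_id, contig, start, end, strand)`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Intergenic spacing between two genes
#'
#' `spacing = b.start - a.end - 1` for gene `a` preceding gene `b` on the
#' same contig: 0 for book-ended genes, negative (<= -1) for overlapping
#' genes, which count as distance 0 for linkage.
#'
#' @param a,b Single-row gene models (`contig`, `start`, `end`).
#' @return Spacing in base pairs (possibly negative).
#' @examples
#' a <- data.frame(gene_id = "a", contig = "c", start = 1, end = 500, strand = "+")
#' b <- data.frame(gene_id = "b", contig = "c", start = 560, end = 900, strand = "+")
#' intergenic_spacing(a, b) # 59
#' @export
intergenic_spacing <- function(a, b) {
  if (a$contig != b$contig) stop("genes lie on different contigs")
  b$start - a$end - 1
}

#' Find genetically linked gene groups
#'
#' Partitions genes into maximal runs of genes that are adjacent in genomic
#' order, colinear (same strand), and separated by an intergenic spacing
#' strictly smaller than `max_spacing` (overlaps count as distance 0).
#' Genes failing to link with either neighbor form singleton groups. Input
#' order does not matter; genes are sorted per contig by start internally.
#'
#' @param genes `data.frame(gene_id, contig, start, end, strand)`.
#' @param max_spacing Strict spacing threshold in bp (default 100).
#' @return `data.frame(group_id, contig, strand, gene_id, position)` —
#'   `position` is the 1-based rank within the group; groups partition the
#'   input gene set.
#' @export
find_linked_groups <- function(genes, max_spacing = 100) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in%
                  names(genes)),
            !anyDuplicated(genes$gene_id))
  genes <- genes[order(genes$contig, genes$start, genes$end), ]
  gid <- 0L
  out <- lapply(split(genes, genes$contig, drop = TRUE), function(d) {
    n <- nrow(d)
    new_group <- c(TRUE, if (n > 1) {
      spacing <- d$start[-1] - d$end[-n] - 1
      linked_dist <- pmax(spacing, 0)  # overlaps count as distance 0
      !(d$strand[-1] == d$strand[-n] & linked_dist < max_spacing)
    })
    grp <- cumsum(new_group)
    data.frame(
      local_group = grp, contig = d$contig, strand = d$strand,
      gene_id = d$gene_id,
      position = stats::ave(seq_len(n), grp, FUN = seq_along)
    )
  })
  res <- do.call(rbind, out)
  # renumber groups globally, in genomic order
  key <- paste(res$contig, res$local_group)
  res$group_id <- paste0("LG", formatC(match(key, unique(key)), width = 4,
                                       flag = "0"))
  res$local_group <- NULL
  rownames(res) <- NULL
  res[, c("group_id", "contig", "strand", "gene_id", "position")]
}

#' Annotate a signature with linkage groups
#'
#' Labels each signature gene with its linkage group and lists the group
#' co-members that are themselves in the signature (evidence that a
#' signature hit may reflect a co-transcribed operon rather than an
#' independent gene). Signature genes absent from the annotation are flagged.
#'
#' @param sig Signature (see [signature_genes()]).
#' @param groups Output of [find_linked_groups()].
#' @return `data.frame(gene_id, direction, group_id, group_size,
#'   co_members, missing)` — `co_members` is a comma-separated list of other
#'   signature genes in the same group (empty when none).
#' @export
annotate_signature <- function(sig, groups) {
  g <- signature_genes(sig)
  idx <- match(g$gene_id, groups$gene_id)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " signature gene(s) missing from the annotation")
  }
  gsz <- table(groups$group_id)
  grp <- groups$group_id[idx]
  co <- vapply(seq_along(grp), function(i) {
    if (is.na(grp[i])) return("")
    members <- groups$gene_id[groups$group_id == grp[i]]
    paste(setdiff(intersect(members, g$gene_id), g$gene_id[i]),
          collapse = ",")
  }, character(1))
  data.frame(
    gene_id = g$gene_id, direction = g$direction,
    group_id = grp,
    group_size = as.integer(gsz[grp]),
    co_members = co,
    missing = missing
  )
}
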