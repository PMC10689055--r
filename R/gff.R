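#' Read gene models from a GFF3 file
#'
#' Imports a GFF3 file via \pkg{rtracklayer}, keeps features of the requested
#' type (default `"gene"`), and converts the 1-based inclusive GFF coordinates
#' to the package-internal 0-based half-open convention. Strand is retained
#' but ignored by all overlap operations.
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return data.frame of class `gene_models` with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and `strand`. Empty (with a warning)
#'   when no feature of the requested type exists.
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stopf("GFF3 not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("malformed GFF3 '%s': %s",
                                           path, conditionMessage(e)))
  gr <- gr[as.character(gr$type) == feature_type]
  if (!length(gr)) {
    warnf("no '%s' features in '%s'", feature_type, path)
    return(gene_models(character(), character(), numeric(), numeric()))
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  ids[is.na(ids)] <- sprintf("gene_%05d", which(is.na(ids)))
  gene_models(gene_id = ids,
              chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr),
              strand = as.character(GenomicRanges::strand(gr)))
}

#' Construct a gene-model table
#'
#' @param gene_id gene identifiers.
#' @param chrom chromosome per gene.
#' @param start,end 0-based half-open coordinates; `start < end` required.
#' @param strand strand per gene (`"+"`, `"-"` or `"*"`); informational only.
#' @return data.frame of class `gene_models`, sorted by chromosome and start.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand = "*") {
  if (length(gene_id) && any(end <= start))
    stopf("gene model with end <= start (first: %s)",
          gene_id[which(end <= start)[1]])
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(gene_id)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models back to GFF3 (1-based inclusive coordinates)
#'
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tpopsweep\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, as.integer(genes$start) + 1L,
                     as.integer(genes$end), genes$strand, genes$gene_id))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
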