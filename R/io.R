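#' Write sequences to FASTA
#'
#' @param seqs named character vector (nucleotide or amino acid).
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write gene models as GTF
#'
#' Emits `exon` and `CDS` features (1-based, inclusive) with `gene_id`
#' and `transcript_id` attributes, one pair of rows per isoform exon, in
#' deterministic order. The whole mature transcript is treated as coding;
#' a recorded 3' CDS trim shortens the CDS rows of the affected isoform.
#'
#' @param models list of [gene_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (model in models) {
    for (iso in names(model$isoforms)) {
      e <- model$exons[match(model$isoforms[[iso]], model$exons$exon_id)]
      cb <- cds_blocks(model, iso)
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                          model$gene_id, iso)
      lines <- c(lines,
                 sprintf("%s\tisocover\texon\t%d\t%d\t.\t%s\t.\t%s",
                         model$chrom, e$start, e$end, model$strand, attr_str),
                 sprintf("%s\tisocover\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                         model$chrom, cb$start, cb$end, model$strand, attr_str))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports `exon` features (via `rtracklayer`) grouped by
#' `transcript_id`/`gene_id` and reconstructs [gene_model()] objects.
#' Exons identical in coordinates are merged into shared exon records
#' within a gene.
#'
#' @param path GTF file.
#' @return named list of [gene_model()].
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  raw <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    gene_id = gr$gene_id,
                    transcript_id = gr$transcript_id,
                    stringsAsFactors = FALSE)
  models <- list()
  for (gid in unique(raw$gene_id)) {
    g <- raw[raw$gene_id == gid, ]
    ex <- unique(g[, c("start", "end")])
    ex <- ex[order(ex$start), ]
    exons <- data.table::data.table(
      exon_id = sprintf("%se%02d", gid, seq_len(nrow(ex))),
      start = as.integer(ex$start), end = as.integer(ex$end))
    strand <- g$strand[1]
    isoforms <- list()
    for (tid in unique(g$transcript_id)) {
      t <- g[g$transcript_id == tid, ]
      t <- if (strand == "+") t[order(t$start), ] else t[order(-t$start), ]
      isoforms[[tid]] <- exons$exon_id[match(paste(t$start, t$end),
                                             paste(exons$start, exons$end))]
    }
    models[[gid]] <- gene_model(gid, g$chrom[1], strand, exons, isoforms)
  }
  models
}

#' Write a table as TSV
#'
#' List-columns are collapsed with `;`. 1-based inclusive coordinates
#' are used throughout tabular output.
#'
#' @param x `data.frame`; @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  x <- data.table::as.data.table(x)
  for (col in names(x))
    if (is.list(x[[col]]))
      x[[col]] <- vapply(x[[col]], paste, character(1), collapse = ";")
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Read a TSV table
#' @param path input file.
#' @return `data.table`.
#' @export
read_tsv <- function(path) data.table::fread(path, sep = "\t")
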