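#' Nondegenerate codon map
#'
#' A bijection from the 20 standard amino acids to a single codon each
#' (default: the most frequent human codon per residue). Because the map
#' is injective and stop-free, reverse-translated peptides occupy an
#' alphabet-inflated copy of peptide space and any fixed map yields an
#' isomorphic assembly graph.
#'
#' @param table named character vector of 20 codons, names = residues.
#' @return named character vector of class `codon_map`.
#' @export
codon_map <- function(table = NULL) {
  if (is.null(table))
    table <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
               G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
               M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "AGA",
               S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")
  stopifnot(length(table) == 20L,
            setequal(names(table), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
            !anyDuplicated(table),
            all(nchar(table) == 3L))
  aa <- vapply(table, translate_nt, character(1))
  if (any(aa != names(table)))
    stop("codon map contains a codon that does not translate to its residue (or a stop)")
  structure(table[sort(names(table))], class = "codon_map")
}

#' Reverse-translate peptides into nucleotide reads
#'
#' Each peptide becomes one read of `3 * nchar(peptide)` nucleotides
#' through the nondegenerate codon map, truncated at `max_read_len`
#' (default 150 nt, i.e. 50 residues). Peptides containing residues
#' outside the 20-letter alphabet are dropped; the drop and truncation
#' counts are reported in attributes `n_dropped` / `n_truncated`.
#'
#' @param peptides character vector of peptide sequences.
#' @param map a [codon_map()].
#' @param max_read_len maximum read length in nucleotides.
#' @return character vector of reads, one per retained peptide (named by
#'   the source peptide).
#' @export
reverse_translate <- function(peptides, map = codon_map(),
                              max_read_len = 150L) {
  stopifnot(inherits(map, "codon_map"))
  ok <- !grepl(paste0("[^", paste(names(map), collapse = ""), "]"), peptides)
  kept <- peptides[ok]
  reads <- vapply(kept, function(p) {
    paste(map[strsplit(p, "", fixed = TRUE)[[1]]], collapse = "")
  }, character(1))
  n_trunc <- sum(nchar(reads) > max_read_len)
  reads <- substr(reads, 1L, max_read_len)
  names(reads) <- kept
  data.table::setattr(reads, "n_dropped", sum(!ok))
  data.table::setattr(reads, "n_truncated", n_trunc)
  reads
}

#' Minimal deterministic de Bruijn unitig assembler
#'
#' Builds the k-mer graph of the reads (nodes are (k-1)-mers, edges are
#' k-mers) and emits every maximal non-branching path (unitig) of length
#' at least `min_contig` nucleotides. No tip or bubble removal is
#' performed, so output is a pure function of the k-mer *set*:
#' independent of read order and duplication. Isolated cycles are broken
#' deterministically at their lexicographically smallest k-mer.
#'
#' @param reads character vector of nucleotide reads.
#' @param k k-mer length (default 23 nt, at least 8 spanned residues).
#' @param min_contig minimum contig length in nt (default 100, at least
#'   34 spanned residues).
#' @return character vector of contigs, lexicographically sorted.
#' @export
assemble <- function(reads, k = 23L, min_contig = 100L) {
  stopifnot(k >= 2L, min_contig >= k)
  reads <- reads[nchar(reads) >= k]
  if (!length(reads)) return(character(0))
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    substring(r, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- sort(unique(kmers))
  pre <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  nodes <- sort(unique(c(pre, suf)))
  pre_i <- match(pre, nodes)
  suf_i <- match(suf, nodes)
  outdeg <- tabulate(pre_i, nbins = length(nodes))
  indeg <- tabulate(suf_i, nbins = length(nodes))
  # unique outgoing edge of each node (NA when outdeg != 1)
  out_edge <- rep(NA_integer_, length(nodes))
  idx1 <- which(outdeg[pre_i] == 1L)
  out_edge[pre_i[idx1]] <- idx1
  simple <- indeg == 1L & outdeg == 1L
  # edge e extends to nxt[e] iff its sink node is simple
  nxt <- ifelse(simple[suf_i], out_edge[suf_i], NA_integer_)
  # chain starts: edges whose source node is not simple
  start <- which(!simple[pre_i])
  visited <- logical(length(kmers))
  contigs <- character(0)
  emit <- function(chain) {
    paste0(nodes[pre_i[chain[1]]],
           paste(substr(kmers[chain], k, k), collapse = ""))
  }
  for (e0 in start) {
    chain <- integer(0)
    e <- e0
    while (!is.na(e) && !visited[e]) {
      visited[e] <- TRUE
      chain <- c(chain, e)
      e <- nxt[e]
    }
    contigs <- c(contigs, emit(chain))
  }
  # leftover edges belong to fully simple cycles; break at smallest k-mer
  while (any(!visited)) {
    e0 <- which(!visited)[1L]                  # kmers are sorted
    chain <- integer(0)
    e <- e0
    while (!is.na(e) && !visited[e]) {
      visited[e] <- TRUE
      chain <- c(chain, e)
      e <- nxt[e]
    }
    contigs <- c(contigs, emit(chain))
  }
  sort(contigs[nchar(contigs) >= min_contig])
}

#' Match assembled scaffolds back to the proteome
#'
#' Translates each scaffold and searches for it in the proteome by brute
#' force string matching. Because a unitig can start at any phase within
#' a codon, all three frames are tried; a scaffold is correct iff some
#' frame's translation is an exact substring of at least one proteome
#' entry. The residue span of a scaffold is `ceiling(nt_length / 3)`
#' (residues overlapped by the nucleotide sequence).
#'
#' @param scaffolds character vector of nucleotide contigs.
#' @param proteome named character vector of protein sequences.
#' @return list: `matches` (`data.table`: `scaffold_id`, `nt_len`,
#'   `aa_span`, `frame`, `aa_seq`, `correct`, `proteins` list-column),
#'   `summary` (list: `n_scaffolds`, `n_correct`, `pct_correct`,
#'   `proteins_hit`, `median_length_nt`), `coverage` (per-protein de novo
#'   coverage via [observed_coverage()], matched scaffolds only).
#' @export
match_scaffolds <- function(scaffolds, proteome) {
  if (!length(scaffolds)) {
    empty <- data.table::data.table(scaffold_id = character(0),
                                    nt_len = integer(0), aa_span = integer(0),
                                    frame = integer(0), aa_seq = character(0),
                                    correct = logical(0), proteins = list())
    return(list(matches = empty,
                summary = list(n_scaffolds = 0L, n_correct = 0L,
                               pct_correct = NA_real_, proteins_hit = 0L,
                               median_length_nt = NA_real_),
                coverage = NULL))
  }
  rows <- lapply(seq_along(scaffolds), function(i) {
    s <- scaffolds[i]
    best <- list(frame = 0L, aa = translate_nt(s), hits = character(0))
    for (f in 0:2) {
      aa <- translate_nt(substr(s, f + 1L, nchar(s)))
      if (!nchar(aa)) next
      hits <- names(proteome)[vapply(proteome, function(p)
        grepl(aa, p, fixed = TRUE), logical(1))]
      if (length(hits)) { best <- list(frame = f, aa = aa, hits = hits); break }
    }
    data.table::data.table(scaffold_id = sprintf("scaffold_%05d", i),
                           nt_len = nchar(s),
                           aa_span = as.integer(ceiling(nchar(s) / 3)),
                           frame = best$frame, aa_seq = best$aa,
                           correct = length(best$hits) > 0L,
                           proteins = list(best$hits))
  })
  matches <- data.table::rbindlist(rows)
  cov <- NULL
  ok <- matches[correct == TRUE]
  if (nrow(ok)) {
    ev <- data.table::rbindlist(lapply(seq_len(nrow(ok)), function(r)
      data.table::data.table(sequence = ok$aa_seq[r],
                             protein_id = ok$proteins[[r]])))
    cov <- observed_coverage(ev, proteome)
  }
  list(matches = matches[],
       summary = list(n_scaffolds = nrow(matches),
                      n_correct = sum(matches$correct),
                      pct_correct = 100 * mean(matches$correct),
                      proteins_hit = length(unique(unlist(ok$proteins))),
                      median_length_nt = stats::median(matches$nt_len)),
       coverage = cov)
}
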