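#' Variant filter thresholds
#'
#' The filter cascade applied to read pileups before a site is accepted
#' as a candidate single-amino-acid polymorphism: total depth >= 10,
#' variant reads >= 5, variant-read frequency >= 15%, base and mapping
#' quality >= 13, and no multi-mapped support.
#'
#' @param min_depth,min_alt,min_freq,min_baseq,min_mapq thresholds.
#' @param drop_multimapped reject sites flagged as multi-mapped.
#' @return list of class `variant_filter`.
#' @export
variant_filter <- function(min_depth = 10L, min_alt = 5L, min_freq = 0.15,
                           min_baseq = 13, min_mapq = 13,
                           drop_multimapped = TRUE) {
  structure(list(min_depth = min_depth, min_alt = min_alt,
                 min_freq = min_freq, min_baseq = min_baseq,
                 min_mapq = min_mapq, drop_multimapped = drop_multimapped),
            class = "variant_filter")
}

#' Filter pileup rows into passing variant calls
#'
#' @param pileup `data.frame` with columns `CHROM`, `POS`, `REF`, `ALT`,
#'   `DEPTH`, `ALT_COUNT`, `BASEQ`, `MAPQ`, `MULTIMAPPED` (logical or
#'   0/1).
#' @param filter a [variant_filter()].
#' @return the passing rows as a `data.table`, with a logical `pass`
#'   vector over all input rows in attribute `pass`.
#' @export
filter_variants <- function(pileup, filter = variant_filter()) {
  need <- c("CHROM", "POS", "REF", "ALT", "DEPTH", "ALT_COUNT",
            "BASEQ", "MAPQ", "MULTIMAPPED")
  missing <- setdiff(need, names(pileup))
  if (length(missing))
    stop("pileup lacks column(s): ", paste(missing, collapse = ", "))
  p <- data.table::as.data.table(pileup)
  bad <- which(!is.finite(p$DEPTH) | !is.finite(p$ALT_COUNT) |
               p$DEPTH < 0 | p$ALT_COUNT < 0 | p$ALT_COUNT > p$DEPTH)
  if (length(bad))
    stop("malformed pileup row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  pass <- p$DEPTH >= filter$min_depth &
    p$ALT_COUNT >= filter$min_alt &
    (p$ALT_COUNT / pmax(p$DEPTH, 1L)) >= filter$min_freq &
    p$BASEQ >= filter$min_baseq &
    p$MAPQ >= filter$min_mapq &
    (!filter$drop_multimapped | !(as.logical(p$MULTIMAPPED)))
  out <- p[pass]
  data.table::setattr(out, "pass", pass)
  out[]
}

# ---- protein consequence and variant proteome ------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

genomic_to_cds <- function(blocks, strand, pos) {
  # blocks in transcript order; returns 1-based CDS index or NA
  lens <- blocks$end - blocks$start + 1L
  off <- cumsum(c(0L, lens))
  for (i in seq_len(nrow(blocks))) {
    if (pos >= blocks$start[i] && pos <= blocks$end[i]) {
      within <- if (strand == "+") pos - blocks$start[i] else blocks$end[i] - pos
      return(off[i] + within + 1L)
    }
  }
  NA_integer_
}

translate_nt <- function(nt) {
  if (nchar(nt) < 3L) return("")
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Protein-level consequence of a genomic substitution
#'
#' @param model a [gene_model()].
#' @param isoform isoform name.
#' @param genome named character vector of chromosome sequences.
#' @param pos,ref,alt 1-based genomic position and alleles (genomic
#'   strand).
#' @return list: `coding` (position inside the isoform CDS), `aa_pos`,
#'   `ref_aa`, `alt_aa`, `synonymous`; `NULL` aa fields when non-coding.
#' @export
variant_consequence <- function(model, isoform, genome, pos, ref, alt) {
  bl <- cds_blocks(model, isoform)
  ci <- genomic_to_cds(bl, model$strand, pos)
  if (is.na(ci))
    return(list(coding = FALSE, aa_pos = NA_integer_,
                ref_aa = NA_character_, alt_aa = NA_character_,
                synonymous = NA))
  cds <- extract_cds(model, isoform, genome)
  ref_cds <- if (model$strand == "+") ref else unname(COMPLEMENT[ref])
  alt_cds <- if (model$strand == "+") alt else unname(COMPLEMENT[alt])
  if (substr(cds, ci, ci) != ref_cds)
    stop("reference allele mismatch at ", model$chrom, ":", pos)
  aa_pos <- as.integer((ci - 1L) %/% 3L) + 1L
  c0 <- (aa_pos - 1L) * 3L + 1L
  codon_ref <- substr(cds, c0, c0 + 2L)
  codon_alt <- codon_ref
  substr(codon_alt, ci - c0 + 1L, ci - c0 + 1L) <- alt_cds
  ref_aa <- translate_nt(codon_ref)
  alt_aa <- translate_nt(codon_alt)
  list(coding = TRUE, aa_pos = aa_pos, ref_aa = ref_aa, alt_aa = alt_aa,
       synonymous = identical(ref_aa, alt_aa))
}

#' Extract the CDS nucleotide sequence of an isoform from the genome
#'
#' @inheritParams variant_consequence
#' @return character CDS in transcript orientation (reverse-complemented
#'   for minus-strand genes).
#' @export
extract_cds <- function(model, isoform, genome) {
  bl <- cds_blocks(model, isoform)
  chrom <- genome[[model$chrom]]
  pieces <- substring(chrom, bl$start, bl$end)
  if (model$strand == "-")
    pieces <- vapply(pieces, function(p)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
      character(1))
  paste(pieces, collapse = "")
}

#' Build the variant proteome from passing calls
#'
#' Applies each passing call to every isoform whose CDS contains it. A
#' synonymous change produces no entry; each nonsynonymous call yields
#' exactly one mutated protein entry per affected isoform, carrying a
#' single substituted residue and a `VAR=<ref_aa><aa_pos><alt_aa>` header
#' annotation. Calls outside any CDS are recorded as non-coding.
#'
#' @param models list of [gene_model()].
#' @param genome named character vector of chromosome sequences.
#' @param calls passing pileup rows (see [filter_variants()]).
#' @return list: `proteins` (named character, names
#'   `<isoform>|VAR=<aa change>`), `table` (`data.table`: `chrom`, `pos`,
#'   `ref`, `alt`, `isoform`, `coding`, `synonymous`, `aa_pos`, `ref_aa`,
#'   `alt_aa`, `entry`).
#' @export
build_variant_proteome <- function(models, genome, calls) {
  calls <- data.table::as.data.table(calls)
  prot <- character(0)
  rows <- list()
  span <- vapply(models, function(m)
    c(min(m$exons$start), max(m$exons$end)), numeric(2))
  for (r in seq_len(nrow(calls))) {
    pos <- calls$POS[r]; chrom <- calls$CHROM[r]
    ref <- calls$REF[r]; alt <- calls$ALT[r]
    hit <- FALSE
    for (k in seq_along(models)) {
      model <- models[[k]]
      if (model$chrom != chrom || pos < span[1, k] || pos > span[2, k]) next
      for (iso in names(model$isoforms)) {
        cons <- variant_consequence(model, iso, genome, pos, ref, alt)
        if (!cons$coding) next
        hit <- TRUE
        entry <- NA_character_
        if (!cons$synonymous) {
          base <- translate_nt(extract_cds(model, iso, genome))
          mutated <- base
          substr(mutated, cons$aa_pos, cons$aa_pos) <- cons$alt_aa
          varname <- paste0(cons$ref_aa, cons$aa_pos, cons$alt_aa)
          entry <- paste0(iso, "|VAR=", varname)
          prot[entry] <- mutated
        }
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = chrom, pos = pos, ref = ref, alt = alt, isoform = iso,
          coding = TRUE, synonymous = cons$synonymous,
          aa_pos = cons$aa_pos, ref_aa = cons$ref_aa, alt_aa = cons$alt_aa,
          entry = entry)
      }
    }
    if (!hit)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        isoform = NA_character_, coding = FALSE, synonymous = NA,
        aa_pos = NA_integer_, ref_aa = NA_character_,
        alt_aa = NA_character_, entry = NA_character_)
  }
  table <- if (length(rows)) data.table::rbindlist(rows)
  else data.table::data.table(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              isoform = character(0), coding = logical(0),
                              synonymous = logical(0), aa_pos = integer(0),
                              ref_aa = character(0), alt_aa = character(0),
                              entry = character(0))
  list(proteins = prot, table = table[])
}

#' Classify peptides against reference and variant proteomes
#'
#' Reproduces the Mutated-column semantics of variation-aware searches:
#' a peptide is `"Yes"` when it arises from a mutated entry (it covers a
#' substituted residue with the variant amino acid) and is absent from
#' the reference proteome; `"Mixed"` when it both covers a substituted
#' residue and occurs somewhere in the reference proteome; `"No"` when it
#' only matches the reference. A SAP counts as proteomics-detected iff at
#' least one `"Yes"` peptide covers its substituted residue.
#'
#' @param evidence `data.frame` with a `sequence` column (extra columns
#'   pass through).
#' @param reference named character vector: reference proteome.
#' @param variant result of [build_variant_proteome()] (or a named
#'   character vector of mutated entries named `<isoform>|VAR=<change>`).
#' @return list: `peptides` (`data.table`: `sequence`, `status`,
#'   `mutations`), `saps` (`data.table` per mutated entry: `entry`,
#'   `detected`, `n_yes_peptides`).
#' @export
classify_sap_peptides <- function(evidence, reference, variant) {
  vprot <- if (is.list(variant) && !is.null(variant$proteins)) variant$proteins
  else variant
  seqs <- unique(evidence$sequence)
  ref_cat <- paste(reference, collapse = "\x01")
  var_pos <- vapply(names(vprot), function(e)
    as.integer(gsub("^.*\\|VAR=[A-Z*]([0-9]+)[A-Z*]$", "\\1", e)), integer(1))
  vprot_vec <- unlist(vprot)
  status <- character(length(seqs))
  muts <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    pep <- seqs[k]
    in_ref <- grepl(pep, ref_cat, fixed = TRUE)
    covers <- character(0)
    # cheap vectorised prefilter before the (overlap-aware) position scan
    cand <- names(vprot)[grepl(pep, vprot_vec, fixed = TRUE)]
    for (e in cand) {
      hits <- Biostrings::matchPattern(pep, Biostrings::AAString(vprot[[e]]))
      if (!length(hits)) next
      vp <- var_pos[[e]]
      if (any(IRanges::start(hits) <= vp & IRanges::end(hits) >= vp))
        covers <- c(covers, e)
    }
    if (length(covers)) {
      status[k] <- if (in_ref) "Mixed" else "Yes"
      muts[[k]] <- covers
    } else {
      status[k] <- "No"
      muts[[k]] <- character(0)
    }
  }
  peptides <- data.table::data.table(sequence = seqs, status = status,
                                     mutations = muts)
  yes <- peptides[status == "Yes"]
  saps <- data.table::data.table(entry = names(vprot))
  saps[, n_yes_peptides := vapply(entry, function(e)
    sum(vapply(yes$mutations, function(m) e %in% m, logical(1))), integer(1))]
  saps[, detected := n_yes_peptides > 0L]
  list(peptides = peptides[], saps = saps[])
}

# ---- deleteriousness shift -------------------------------------------------

#' Two-sided Wilcoxon rank-sum test with tie correction
#'
#' Normal approximation of the rank-sum test used to compare
#' deleteriousness scores of proteomics-detected versus undetected SAPs.
#' Ties are handled by midranks with the standard variance correction; a
#' fully tied input (zero variance) returns p = 1.
#'
#' @param x,y numeric score vectors (e.g. SIFT or PolyPhen raw scores for
#'   detected and undetected variants).
#' @return list: `statistic` (rank-sum W of `x`), `u` (Mann-Whitney U),
#'   `z`, `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) return(list(statistic = W, u = U, z = 0, p_value = 1))
  z <- (U - mu) / sqrt(v)
  list(statistic = W, u = U, z = z,
       p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Deleteriousness shift between detected and undetected SAPs
#'
#' Compares externally computed deleteriousness scores (SIFT, PolyPhen)
#' of proteomics-detected versus transcript-only SAPs with the two-sided
#' rank-sum test, and tabulates category fractions from configurable
#' cut-points. The default SIFT bins are deleterious (< 0.05),
#' potentially deleterious (< 0.10), borderline (< 0.20) and tolerant;
#' the default PolyPhen bins are the published benign (<= 0.446),
#' possibly damaging (<= 0.908) and probably damaging categories.
#'
#' @param scores_detected,scores_undetected numeric score vectors.
#' @param breaks increasing internal cut-points.
#' @param labels category labels, `length(breaks) + 1`.
#' @return list: `p_value`, `statistic`, `fractions` (`data.table`:
#'   `group`, `category`, `fraction`).
#' @export
deleteriousness_shift <- function(scores_detected, scores_undetected,
                                  breaks = c(0.05, 0.1, 0.2),
                                  labels = c("deleterious",
                                             "potentially deleterious",
                                             "borderline", "tolerant")) {
  stopifnot(length(labels) == length(breaks) + 1L)
  tst <- rank_sum_test(scores_detected, scores_undetected)
  catf <- function(s, group) {
    cat <- cut(s, breaks = c(-Inf, breaks, Inf), labels = labels,
               right = FALSE)
    data.table::data.table(group = group, category = labels,
                           fraction = as.numeric(table(cat)[labels]) / length(s))
  }
  fractions <- rbind(catf(scores_detected, "detected"),
                     catf(scores_undetected, "undetected"))
  list(p_value = tst$p_value, statistic = tst$statistic,
       fractions = fractions[])
}
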