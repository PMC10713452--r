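#' Observed protein sequence coverage from peptide evidence
#'
#' For every evidence row, the peptide sequence is searched for all
#' occurrences (overlapping included) in the designated protein, ignoring
#' enzyme specificity, and every residue touched by at least one
#' occurrence is marked as observed. Coverage is the marked fraction of
#' the protein length.
#'
#' @param evidence `data.frame` with at least `sequence` and `protein_id`
#'   columns; extra columns such as `protease`, `cell_line` or per-run PSM
#'   counts may be used through `subset`.
#' @param proteome named character vector of protein sequences.
#' @param subset optional named list of column filters, e.g.
#'   `list(protease = "trypsin")`; only rows matching every filter
#'   contribute.
#' @param keep_mask keep the per-protein covered-position masks (logical
#'   vectors) in the result attribute `masks`.
#' @return `data.table` with `protein_id`, `length`, `covered`,
#'   `coverage`, `n_peptides` (distinct contributing sequences). Rows with
#'   peptides absent from their protein are skipped with one warning; the
#'   skip count is in attribute `n_skipped`.
#' @export
observed_coverage <- function(evidence, proteome, subset = NULL,
                              keep_mask = FALSE) {
  stopifnot(all(c("sequence", "protein_id") %in% names(evidence)))
  ev <- data.table::as.data.table(evidence)
  if (!is.null(subset)) {
    for (col in names(subset)) {
      if (!col %in% names(ev)) stop("subset column not in evidence: ", col)
      ev <- ev[ev[[col]] %in% subset[[col]]]
    }
  }
  unknown <- setdiff(unique(ev$protein_id), names(proteome))
  if (length(unknown))
    stop("evidence names protein(s) absent from the proteome: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  masks <- lapply(proteome, function(s) logical(nchar(s)))
  npep <- stats::setNames(vector("list", length(proteome)), names(proteome))
  n_skipped <- 0L
  if (nrow(ev)) {
    uq <- unique(ev[, list(sequence, protein_id)])
    for (r in seq_len(nrow(uq))) {
      pid <- uq$protein_id[r]
      pep <- uq$sequence[r]
      hits <- Biostrings::matchPattern(pep, Biostrings::AAString(proteome[[pid]]))
      if (length(hits) == 0L) {
        n_skipped <- n_skipped + 1L
        next
      }
      for (h in seq_along(hits))
        masks[[pid]][IRanges::start(hits)[h]:IRanges::end(hits)[h]] <- TRUE
      npep[[pid]] <- c(npep[[pid]], pep)
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " evidence peptide(s) not found in their designated protein; skipped")
  out <- data.table::data.table(
    protein_id = names(proteome),
    length = as.integer(nchar(proteome)),
    covered = vapply(masks, sum, integer(1)),
    n_peptides = vapply(npep, function(x) length(unique(x)), integer(1)))
  out[, coverage := ifelse(length > 0L, covered / length, 0)]
  data.table::setcolorder(out, c("protein_id", "length", "covered",
                                 "coverage", "n_peptides"))
  data.table::setattr(out, "n_skipped", n_skipped)
  if (keep_mask) data.table::setattr(out, "masks", masks)
  out[]
}

#' Protease-combination coverage scan
#'
#' Scores every subset of proteases of the requested sizes by the median
#' per-protein coverage achieved by pooling their evidence (observed mode)
#' or their in silico digests (theoretical mode), and ranks subsets within
#' each size. Ties are broken lexicographically on the sorted protease
#' names, so the ranking is deterministic.
#'
#' @param evidence evidence table with a `protease` column (observed
#'   mode), or `NULL` to score theoretical digests.
#' @param proteome named character vector of protein sequences.
#' @param proteases protease names to scan; defaults to those present in
#'   the evidence, or the full six-enzyme panel in theoretical mode.
#' @param sizes subset sizes to score (default 2:5).
#' @param rules,params used in theoretical mode (see
#'   [theoretical_coverage()]).
#' @param top keep the `top` best subsets per size in `$top`; all scored
#'   subsets are returned in `$all`.
#' @return list with `all` and `top` `data.table`s (`size`, `proteases`,
#'   `median_coverage`, `rank`).
#' @export
combination_scan <- function(evidence = NULL, proteome, proteases = NULL,
                             sizes = 2:5, rules = NULL,
                             params = digest_params(), top = 3L) {
  theoretical <- is.null(evidence)
  if (theoretical) {
    if (is.null(rules)) rules <- protease_rules()
    if (is.null(proteases)) proteases <- names(rules)
  } else {
    stopifnot("protease" %in% names(evidence))
    if (is.null(proteases)) proteases <- sort(unique(evidence$protease))
  }
  if (length(proteases) < 2L) stop("need at least two proteases to scan")
  sizes <- sizes[sizes <= length(proteases) & sizes >= 1L]
  # per-protease coverage masks, combined by union per subset
  per_masks <- lapply(proteases, function(p) {
    if (theoretical) {
      dt <- digest_proteome(proteome, rules[p], params)
      masks <- lapply(proteome, function(s) logical(nchar(s)))
      if (nrow(dt)) for (r in seq_len(nrow(dt)))
        masks[[dt$protein_id[r]]][dt$start[r]:dt$end[r]] <- TRUE
      masks
    } else {
      cov <- observed_coverage(evidence, proteome,
                               subset = list(protease = p), keep_mask = TRUE)
      attr(cov, "masks")
    }
  })
  names(per_masks) <- proteases
  lens <- nchar(proteome)
  score_subset <- function(ps) {
    fr <- vapply(seq_along(proteome), function(k) {
      m <- Reduce(`|`, lapply(per_masks[ps], `[[`, k))
      if (lens[k] > 0L) sum(m) / lens[k] else 0
    }, numeric(1))
    stats::median(fr)   # linear interpolation for even counts (R default)
  }
  rows <- list()
  for (sz in sizes) {
    subsets <- utils::combn(sort(proteases), sz, simplify = FALSE)
    sc <- vapply(subsets, score_subset, numeric(1))
    lab <- vapply(subsets, paste, character(1), collapse = "+")
    ord <- order(-sc, lab)
    rows[[as.character(sz)]] <- data.table::data.table(
      size = sz, proteases = lab[ord], median_coverage = sc[ord],
      rank = seq_along(ord))
  }
  all <- data.table::rbindlist(rows)
  list(all = all[], top = all[rank <= top][])
}

#' Transmembrane-segment coverage profile
#'
#' Aligns annotated membrane-spanning segments at their N- or C-terminal
#' boundary and averages per-residue observed coverage at each offset from
#' that boundary, producing the positional profile used to compare enzyme
#' performance inside and around transmembrane regions.
#'
#' Offsets are measured in residues: with `anchor = "N"`, offset 0 is the
#' first segment residue and positive offsets run into the segment
#' (towards C); with `anchor = "C"`, offset 0 is the last segment residue
#' and positive offsets run towards N. Negative offsets are outside the
#' segment. Positions falling outside the protein are ignored.
#'
#' @param coverage result of [observed_coverage()] with `keep_mask = TRUE`.
#' @param tm `data.frame` of segments: `protein_id`, `start`, `end`
#'   (1-based inclusive residue coordinates).
#' @param anchor `"N"` or `"C"`.
#' @param offsets integer offsets to profile (default -20:40).
#' @return `data.table` with `offset`, `mean_coverage`, `n_segments`
#'   (segments contributing a valid position at that offset). Empty
#'   annotation input yields an empty table.
#' @export
tm_profile <- function(coverage, tm, anchor = c("N", "C"), offsets = -20:40) {
  anchor <- match.arg(anchor)
  masks <- attr(coverage, "masks")
  if (is.null(masks))
    stop("coverage must be produced with observed_coverage(..., keep_mask = TRUE)")
  tm <- data.table::as.data.table(tm)
  if (nrow(tm) == 0L)
    return(data.table::data.table(offset = integer(0),
                                  mean_coverage = numeric(0),
                                  n_segments = integer(0)))
  stopifnot(all(tm$protein_id %in% names(masks)))
  acc <- numeric(length(offsets)); cnt <- integer(length(offsets))
  for (r in seq_len(nrow(tm))) {
    m <- masks[[tm$protein_id[r]]]
    pos <- if (anchor == "N") tm$start[r] + offsets else tm$end[r] - offsets
    ok <- pos >= 1L & pos <= length(m)
    acc[ok] <- acc[ok] + as.numeric(m[pos[ok]])
    cnt[ok] <- cnt[ok] + 1L
  }
  data.table::data.table(offset = offsets,
                         mean_coverage = ifelse(cnt > 0L, acc / cnt, NA_real_),
                         n_segments = cnt)
}
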