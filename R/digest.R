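#' Protease cleavage rules
#'
#' Construct the cleavage specificity of a protease: the residue set it
#' recognises, whether it cuts on the C- or N-terminal side of that residue,
#' residues that block the cut when they follow it (classically proline),
#' and the maximum number of missed cleavages retained during digestion.
#'
#' @param name protease name (free text; the six standard enzymes are
#'   available pre-configured through [protease_rules()]).
#' @param residues character vector of single-letter amino acids recognised.
#' @param cut_side `"C"` (cut after the residue) or `"N"` (cut before it).
#' @param no_cut_before residues that suppress the cut when they occupy the
#'   position immediately C-terminal of the site. Use `character(0)` to
#'   disable the exception.
#' @param max_missed maximum missed cleavages for this enzyme.
#' @return an object of class `protease_rule`.
#' @export
protease_rule <- function(name, residues, cut_side = c("C", "N"),
                          no_cut_before = character(0), max_missed = 2L) {
  cut_side <- match.arg(cut_side)
  stopifnot(length(residues) >= 1L, max_missed >= 0L)
  structure(list(name = name,
                 residues = toupper(residues),
                 cut_side = cut_side,
                 no_cut_before = toupper(no_cut_before),
                 max_missed = as.integer(max_missed)),
            class = "protease_rule")
}

#' @export
print.protease_rule <- function(x, ...) {
  side <- if (x$cut_side == "C") "C-terminal to" else "N-terminal to"
  cat(sprintf("<protease_rule> %s: cuts %s {%s}%s; max missed %d\n",
              x$name, side, paste(x$residues, collapse = ","),
              if (length(x$no_cut_before))
                paste0(", not before {", paste(x$no_cut_before, collapse = ","), "}")
              else "",
              x$max_missed))
  invisible(x)
}

#' Default rule set for the six-protease panel
#'
#' Standard specificities (MaxQuant defaults): trypsin C-terminal to K/R,
#' LysC C-terminal to K, LysN N-terminal to K, AspN N-terminal to D, GluC
#' C-terminal to E, chymotrypsin C-terminal to F/W/Y/L. The
#' no-cut-before-proline exception is applied to the C-terminal cutters by
#' default and can be switched off. Chymotrypsin allows up to four missed
#' cleavages, all other enzymes two.
#'
#' @param proteases subset of enzyme names to return.
#' @param proline_rule apply the no-cut-before-proline exception to
#'   trypsin, LysC, GluC and chymotrypsin.
#' @return named list of [protease_rule()] objects.
#' @export
protease_rules <- function(proteases = c("trypsin", "LysC", "LysN",
                                         "AspN", "GluC", "chymotrypsin"),
                           proline_rule = TRUE) {
  P <- if (proline_rule) "P" else character(0)
  all <- list(
    trypsin      = protease_rule("trypsin", c("K", "R"), "C", P, 2L),
    LysC         = protease_rule("LysC", "K", "C", P, 2L),
    LysN         = protease_rule("LysN", "K", "N", character(0), 2L),
    AspN         = protease_rule("AspN", "D", "N", character(0), 2L),
    GluC         = protease_rule("GluC", "E", "C", P, 2L),
    chymotrypsin = protease_rule("chymotrypsin", c("F", "W", "Y", "L"), "C", P, 4L)
  )
  missing <- setdiff(proteases, names(all))
  if (length(missing))
    stop("unknown protease(s): ", paste(missing, collapse = ", "))
  all[proteases]
}

#' Digestion parameters
#'
#' Peptide length window used to retain fragments of a size suitable for
#' MS detection (default 7-35 residues).
#'
#' @param min_len,max_len inclusive length bounds in amino acids.
#' @return list of class `digest_params`.
#' @export
digest_params <- function(min_len = 7L, max_len = 35L) {
  stopifnot(min_len <= max_len, min_len >= 1L)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "digest_params")
}

#' Cleavage sites of a protease on a protein
#'
#' Returns the between-residue cut positions (0-based, half-open
#' convention: a site `s` separates residues `1..s` from `s+1..n`), in
#' strictly increasing order. The trivial site 0 is never reported; the
#' site at the C terminus is reported when the final residue is itself a
#' cleavage residue of a C-terminal cutter.
#'
#' Non-standard residues (U, X, B, Z, ...) are treated as non-cleavable
#' and never trigger or block a cut.
#'
#' @param protein amino-acid string.
#' @param rule a [protease_rule()].
#' @return integer vector of cut positions in `1..nchar(protein)`.
#' @export
cleavage_sites <- function(protein, rule) {
  stopifnot(inherits(rule, "protease_rule"))
  n <- nchar(protein)
  if (n == 0L) return(integer(0))
  aa <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  hit <- which(aa %in% rule$residues)
  if (!length(hit)) return(integer(0))
  if (rule$cut_side == "C") {
    sites <- hit                              # cut after residue i -> site i
    if (length(rule$no_cut_before)) {
      nxt <- ifelse(sites < n, aa[pmin(sites + 1L, n)], "")
      sites <- sites[!(nxt %in% rule$no_cut_before)]
    }
  } else {
    sites <- hit - 1L                         # cut before residue i -> site i-1
  }
  sites <- sites[sites >= 1L & sites <= n]
  sort(unique(as.integer(sites)))
}

#' In silico digestion of one protein
#'
#' Enumerates every fragment delimited by two cleavage boundaries (protein
#' termini included) containing at most `max_missed` internal cleavage
#' sites, then optionally applies the MS length window.
#'
#' @param protein amino-acid string.
#' @param rule a [protease_rule()].
#' @param params a [digest_params()] window, or `NULL` for no length filter.
#' @param max_missed override of `rule$max_missed`.
#' @param protein_id optional identifier recorded in the output.
#' @return `data.table` with columns `peptide`, `protein_id`, `start`,
#'   `end` (1-based inclusive residue coordinates) and `n_missed`.
#' @export
digest <- function(protein, rule, params = digest_params(),
                   max_missed = rule$max_missed, protein_id = NA_character_) {
  n <- nchar(protein)
  empty <- data.table::data.table(peptide = character(0),
                                  protein_id = character(0),
                                  start = integer(0), end = integer(0),
                                  n_missed = integer(0))
  if (n == 0L) return(empty)
  sites <- cleavage_sites(protein, rule)
  b <- sort(unique(c(0L, sites[sites < n], n)))   # fragment boundaries
  nb <- length(b)
  # fragment (i, j): residues b[i]+1 .. b[j], internal sites = j - i - 1
  i <- rep.int(seq_len(nb - 1L), times = pmin(max_missed + 1L, (nb - 1L):1L))
  j <- i + sequence(pmin(max_missed + 1L, (nb - 1L):1L))
  dt <- data.table::data.table(start = b[i] + 1L, end = b[j],
                               n_missed = j - i - 1L)
  if (!is.null(params)) {
    len <- dt$end - dt$start + 1L
    dt <- dt[len >= params$min_len & len <= params$max_len]
  }
  if (nrow(dt) == 0L) return(empty)
  dt[, `:=`(peptide = substring(protein, start, end),
            protein_id = protein_id)]
  data.table::setcolorder(dt, c("peptide", "protein_id", "start", "end", "n_missed"))
  dt[]
}

#' Digest a whole proteome with one or more proteases
#'
#' @param proteome named character vector of protein sequences.
#' @param rules list of [protease_rule()] (e.g. [protease_rules()]).
#' @param params a [digest_params()] window or `NULL`.
#' @return `data.table` with an added `protease` column.
#' @export
digest_proteome <- function(proteome, rules, params = digest_params()) {
  stopifnot(length(rules) >= 1L, !is.null(names(proteome)))
  if (inherits(rules, "protease_rule")) rules <- list(rules)
  out <- lapply(rules, function(rule) {
    per <- lapply(names(proteome), function(id)
      digest(proteome[[id]], rule, params, protein_id = id))
    dt <- data.table::rbindlist(per)
    dt[, protease := rule$name]
    dt
  })
  data.table::rbindlist(out)[]
}

#' Theoretical proteome coverage of a protease panel
#'
#' Digests every protein with every rule, keeps fragments inside the
#' length window, and marks each residue contained in at least one
#' retained peptide as covered. Reports the per-protein covered fraction
#' and the aggregate residue counts.
#'
#' @inheritParams digest_proteome
#' @return list with `per_protein` (`data.table`: `protein_id`, `length`,
#'   `covered`, `coverage`), `total_residues`, `covered_residues`,
#'   `aggregate` (covered / total) and `n_unique_peptides` (peptides
#'   deduplicated by sequence across the whole panel).
#' @export
theoretical_coverage <- function(proteome, rules, params = digest_params()) {
  if (inherits(rules, "protease_rule")) rules <- list(rules)
  stopifnot(length(rules) >= 1L)
  ids <- names(proteome)
  lens <- nchar(proteome)
  covered <- integer(length(ids))
  all_peps <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    prot <- proteome[[k]]
    mask <- logical(lens[k])
    seqs <- character(0)
    for (rule in rules) {
      dt <- digest(prot, rule, params)
      if (nrow(dt)) {
        for (r in seq_len(nrow(dt)))
          mask[dt$start[r]:dt$end[r]] <- TRUE
        seqs <- c(seqs, dt$peptide)
      }
    }
    covered[k] <- sum(mask)
    all_peps[[k]] <- unique(seqs)
  }
  per <- data.table::data.table(protein_id = ids, length = as.integer(lens),
                                covered = covered,
                                coverage = ifelse(lens > 0, covered / lens, 0))
  list(per_protein = per,
       total_residues = sum(lens),
       covered_residues = sum(covered),
       aggregate = sum(covered) / max(1L, sum(lens)),
       n_unique_peptides = length(unique(unlist(all_peps))))
}
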