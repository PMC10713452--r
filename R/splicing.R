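#' Gene model
#'
#' A gene with strand, exon records and isoforms given as ordered exon-id
#' lists. Exon coordinates are genomic, 1-based, inclusive. Isoform exon
#' lists are in transcript order: ascending genomic coordinates on the
#' plus strand, descending on the minus strand. The whole mature
#' transcript is assumed coding unless `cds_trim` shortens an isoform's
#' CDS (in nucleotides, from the 3' end; used for frameshift-truncated
#' isoforms).
#'
#' @param gene_id,chrom,strand identifiers; `strand` is `"+"` or `"-"`.
#' @param exons `data.frame` with `exon_id`, `start`, `end`.
#' @param isoforms named list of character vectors of exon ids.
#' @param cds_trim optional named integer vector (per isoform) of
#'   nucleotides to drop from the CDS 3' end.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, isoforms,
                       cds_trim = NULL) {
  stopifnot(strand %in% c("+", "-"),
            all(c("exon_id", "start", "end") %in% names(exons)),
            length(isoforms) >= 1L, !is.null(names(isoforms)))
  exons <- data.table::as.data.table(exons)
  exons[, `:=`(start = as.integer(start), end = as.integer(end),
               exon_id = as.character(exon_id))]
  stopifnot(all(exons$start <= exons$end), !anyDuplicated(exons$exon_id))
  for (iso in names(isoforms)) {
    ids <- isoforms[[iso]]
    stopifnot(all(ids %in% exons$exon_id))
    e <- exons[match(ids, exons$exon_id)]
    ord <- if (strand == "+") order(e$start) else order(-e$start)
    if (!identical(ord, seq_along(ids)))
      stop("isoform ", iso, " exons are not in transcript order")
    eg <- e[order(e$start)]
    if (nrow(eg) > 1L && any(eg$start[-1L] <= eg$end[-nrow(eg)]))
      stop("overlapping exons within isoform ", iso)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, isoforms = isoforms,
                 cds_trim = cds_trim %||% stats::setNames(integer(0), character(0))),
            class = "gene_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s(%s): %d exons, %d isoforms\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), length(x$isoforms)))
  invisible(x)
}

#' CDS blocks of an isoform in transcript order
#'
#' @param model a [gene_model()].
#' @param isoform isoform name.
#' @return `data.table` of genomic blocks (`start`, `end`, 1-based
#'   inclusive, `start <= end`) in transcript (5'->3') order, with the 3'
#'   trim applied when recorded.
#' @export
cds_blocks <- function(model, isoform) {
  ids <- model$isoforms[[isoform]]
  if (is.null(ids)) stop("unknown isoform: ", isoform)
  idx <- match(ids, model$exons$exon_id)
  start <- model$exons$start[idx]
  end <- model$exons$end[idx]
  trim <- model$cds_trim[isoform]
  if (!is.na(trim) && length(trim) && trim > 0L) {
    remaining <- as.integer(trim)
    for (i in rev(seq_along(start))) {        # trim from 3' end
      cut <- min(end[i] - start[i] + 1L, remaining)
      if (model$strand == "+") end[i] <- end[i] - cut
      else start[i] <- start[i] + cut
      remaining <- remaining - cut
      if (remaining == 0L) break
    }
    keep <- end >= start
    start <- start[keep]; end <- end[keep]
  }
  data.frame(start = start, end = end)
}

# ---- splice graph ----------------------------------------------------------

node_id <- function(coord, type) paste0(type, coord)

#' Build the exon-boundary splice graph of a gene
#'
#' Nodes are the beginnings (`S`) and ends (`E`) of exons; edges are
#' intra-exon connections (`S -> E`) and exon-exon junctions (`E -> S`).
#' Shared boundaries collapse into single nodes. Each isoform is a path
#' through the graph; edges record their supporting isoforms. The graph
#' is laid out genomically left-to-right irrespective of strand.
#'
#' @param model a [gene_model()].
#' @return object of class `splice_graph`: `nodes` (`id`, `coord`,
#'   `type`), `edges` (`from`, `to`, `type`, `isoforms` list-column),
#'   `paths` (named list of node-id sequences, genomic order), plus
#'   `gene_id` and `strand`.
#' @export
build_graph <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  paths <- list()
  edges <- list()
  for (iso in names(model$isoforms)) {
    ids <- model$isoforms[[iso]]
    e <- model$exons[match(ids, model$exons$exon_id)]
    e <- e[order(e$start)]                     # genomic order
    nd <- character(0)
    for (i in seq_len(nrow(e))) {
      s <- node_id(e$start[i], "S"); en <- node_id(e$end[i], "E")
      if (i > 1L)
        edges[[length(edges) + 1L]] <-
          list(from = node_id(e$end[i - 1L], "E"), to = s,
               type = "junction", isoform = iso)
      edges[[length(edges) + 1L]] <-
        list(from = s, to = en, type = "intra", isoform = iso)
      nd <- c(nd, s, en)
    }
    paths[[iso]] <- nd
  }
  ed <- data.table::rbindlist(edges)
  ed <- ed[, list(isoforms = list(sort(unique(isoform)))),
           by = list(from, to, type)]
  coords <- as.integer(sub("^[SE]", "", c(ed$from, ed$to)))
  types <- substr(c(ed$from, ed$to), 1L, 1L)
  nodes <- unique(data.table::data.table(id = c(ed$from, ed$to),
                                         coord = coords, type = types))
  data.table::setorder(nodes, coord, -type)    # S before E at equal coord
  structure(list(gene_id = model$gene_id, strand = model$strand,
                 nodes = nodes, edges = ed, paths = paths),
            class = "splice_graph")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("<splice_graph> %s: %d nodes, %d edges, %d isoform paths\n",
              x$gene_id, nrow(x$nodes), nrow(x$edges), length(x$paths)))
  invisible(x)
}

path_exonic_len <- function(path) {
  # exonic nucleotides covered by intra-exon edges along a node-id path
  if (length(path) < 2L) return(0L)
  tot <- 0L
  for (i in seq_len(length(path) - 1L)) {
    a <- path[i]; b <- path[i + 1L]
    if (startsWith(a, "S") && startsWith(b, "E"))
      tot <- tot + (as.integer(sub("^E", "", b)) -
                    as.integer(sub("^S", "", a)) + 1L)
  }
  tot
}

classify_event_type <- function(paths, strand) {
  # paths: list of node-id character vectors sharing first/last nodes
  a <- paths[[1]][1]; b <- paths[[1]][length(paths[[1]])]
  ta <- substr(a, 1, 1); tb <- substr(b, 1, 1)
  lens <- lengths(paths)
  n_full_exons <- vapply(paths, function(p) {
    inner <- p[-c(1L, length(p))]
    sum(startsWith(inner, "S"))                # each inner S starts a full exon
  }, integer(1))
  if (length(paths) == 2L) {
    direct <- lens == 2L
    if (ta == "E" && tb == "S" && any(direct)) {
      other <- n_full_exons[!direct]
      if (length(other) == 1L && other == 1L) return("cassette exon")
      return("other")
    }
    if (ta == "S" && tb == "E" && any(direct)) return("intron retention")
    if (ta == "S" && tb == "S" && all(lens == 3L)) {
      # alternative donor site genomically; 5' on +, 3' on -
      return(if (strand == "+") "alt 5'" else "alt 3'")
    }
    if (ta == "E" && tb == "E" && all(lens == 3L)) {
      return(if (strand == "+") "alt 3'" else "alt 5'")
    }
    if (ta == "E" && tb == "S" && all(lens == 4L) && all(n_full_exons == 1L)) {
      ex1 <- paths[[1]][2]; ex2 <- paths[[2]][2]
      if (ex1 != ex2) return("mutually exclusive")
    }
  }
  "other"
}

#' Enumerate alternative-splicing events in a splice graph
#'
#' An event is a local subgraph in which at least two isoform paths leave
#' a shared anchor node and reconverge only at a shared downstream anchor:
#' for some isoform pair the two anchors are consecutive common nodes and
#' the subpaths between them differ. Events are keyed by their anchor
#' pair; all distinct subpaths observed between the anchors are collected,
#' so an event can carry more than two paths.
#'
#' The event type is assigned from path topology (cassette exon, intron
#' retention, alternative 5'/3' site, mutually exclusive exons, other),
#' and the frame status from the exonic-length difference between the two
#' most distinct paths: frame-preserving iff the inserted length is
#' divisible by 3.
#'
#' @param graph a [build_graph()] result.
#' @return `data.table` with one row per event: `gene_id`, `anchor_start`,
#'   `anchor_end`, `type`, `n_paths`, `frame_preserving`, `delta_nt`
#'   (absolute exonic-length difference) and a `paths` list-column of
#'   node-id vectors (deterministic order: shortest first, then
#'   lexicographic).
#' @export
enumerate_events <- function(graph) {
  stopifnot(inherits(graph, "splice_graph"))
  isos <- names(graph$paths)
  found <- list()
  if (length(isos) >= 2L) {
    for (i in seq_len(length(isos) - 1L)) {
      for (j in (i + 1L):length(isos)) {
        p1 <- graph$paths[[isos[i]]]; p2 <- graph$paths[[isos[j]]]
        common <- p1[p1 %in% p2]
        if (length(common) < 2L) next
        pos1 <- match(common, p1); pos2 <- match(common, p2)
        for (k in seq_len(length(common) - 1L)) {
          s1 <- p1[pos1[k]:pos1[k + 1L]]
          s2 <- p2[pos2[k]:pos2[k + 1L]]
          if (identical(s1, s2)) next
          key <- paste(common[k], common[k + 1L], sep = "|")
          found[[key]] <- unique(c(found[[key]], list(s1), list(s2)))
        }
      }
    }
  }
  if (!length(found))
    return(data.table::data.table(gene_id = character(0),
                                  anchor_start = character(0),
                                  anchor_end = character(0),
                                  type = character(0), n_paths = integer(0),
                                  frame_preserving = logical(0),
                                  delta_nt = integer(0), paths = list()))
  rows <- lapply(names(found), function(key) {
    anch <- strsplit(key, "|", fixed = TRUE)[[1]]
    paths <- found[[key]]
    ord <- order(lengths(paths),
                 vapply(paths, paste, character(1), collapse = ","))
    paths <- paths[ord]
    exlen <- vapply(paths, path_exonic_len, integer(1))
    delta <- max(exlen) - min(exlen)
    data.table::data.table(
      gene_id = graph$gene_id, anchor_start = anch[1], anchor_end = anch[2],
      type = classify_event_type(paths[c(1L, length(paths))], graph$strand),
      n_paths = length(paths),
      frame_preserving = (delta %% 3L) == 0L,
      delta_nt = as.integer(delta), paths = list(paths))
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, anchor_start, anchor_end)
  out[]
}

path_junctions <- function(path) {
  # junction edges (E->S) along a node-id path, as "donor>acceptor" keys
  if (length(path) < 2L) return(character(0))
  a <- path[-length(path)]; b <- path[-1L]
  j <- startsWith(a, "E") & startsWith(b, "S")
  paste0(sub("^E", "", a[j]), ">", sub("^S", "", b[j]))
}

#' Classify every junction of a gene
#'
#' A junction is constitutive iff it appears in every isoform of the
#' gene. Non-constitutive junctions that form the direct skip path of an
#' enumerated event are exclusion junctions; the remaining alternative
#' junctions (those present only in event paths containing extra
#' sequence) are inclusion junctions.
#'
#' @param graph a [build_graph()] result.
#' @param events optional precomputed [enumerate_events()] table.
#' @return `data.table`: `gene_id`, `donor`, `acceptor` (genomic
#'   coordinates, donor < acceptor), `class`.
#' @export
classify_junctions <- function(graph, events = NULL) {
  if (is.null(events)) events <- enumerate_events(graph)
  all_j <- lapply(graph$paths, path_junctions)
  keys <- sort(unique(unlist(all_j)))
  if (!length(keys))
    return(data.table::data.table(gene_id = character(0), donor = integer(0),
                                  acceptor = integer(0), class = character(0)))
  in_all <- vapply(keys, function(k)
    all(vapply(all_j, function(p) k %in% p, logical(1))), logical(1))
  skip_j <- character(0)
  if (nrow(events)) {
    for (r in seq_len(nrow(events))) {
      for (p in events$paths[[r]]) {
        if (length(p) == 2L && startsWith(p[1], "E") && startsWith(p[2], "S"))
          skip_j <- c(skip_j, path_junctions(p))
      }
    }
  }
  cls <- ifelse(in_all, "constitutive",
                ifelse(keys %in% skip_j, "exclusion", "inclusion"))
  parts <- data.table::tstrsplit(keys, ">", fixed = TRUE)
  data.table::data.table(gene_id = graph$gene_id,
                         donor = as.integer(parts[[1]]),
                         acceptor = as.integer(parts[[2]]),
                         class = cls)
}

# ---- peptide projection ----------------------------------------------------

#' Project a peptide onto genomic coordinates
#'
#' Converts protein coordinates of a peptide to genome locations through
#' the intron-exon structure of its source isoform. The nucleotide span is
#' `[3*(aa_start-1), 3*aa_end)` in CDS space, split across the isoform's
#' CDS blocks. Blocks are reported 1-based inclusive, each with
#' `start <= end`, in transcript order (descending genomic coordinates on
#' the minus strand); block lengths always sum to three times the peptide
#' length.
#'
#' @param model a [gene_model()].
#' @param isoform isoform name.
#' @param aa_start,aa_end 1-based inclusive residue coordinates of the
#'   peptide within the isoform's protein.
#' @return list of class `peptide_alignment`: `blocks` (`data.table`
#'   `start`, `end` in transcript order), `junctions` (`data.table`
#'   `donor`, `acceptor`, genomic ascending, with `lnt`/`rnt` nucleotides
#'   of the alignment on the genomically left/right side), `strand`,
#'   `chrom`, `aa_start`, `aa_end`.
#' @export
project_peptide <- function(model, isoform, aa_start, aa_end) {
  stopifnot(aa_start >= 1L, aa_end >= aa_start)
  bl <- cds_blocks(model, isoform)
  lens <- bl$end - bl$start + 1L
  cds_len <- sum(lens)
  r0 <- 3L * (aa_start - 1L); r1 <- 3L * aa_end   # 0-based half-open
  if (r1 > cds_len)
    stop("peptide extends beyond the CDS of isoform ", isoform)
  off <- cumsum(c(0L, lens))[seq_len(nrow(bl))]   # block CDS offsets
  bs <- integer(0); be <- integer(0)
  for (i in seq_len(nrow(bl))) {
    lo <- max(r0, off[i]); hi <- min(r1, off[i] + lens[i])
    if (lo >= hi) next
    if (model$strand == "+") {
      bs <- c(bs, bl$start[i] + (lo - off[i]))
      be <- c(be, bl$start[i] + (hi - off[i]) - 1L)
    } else {
      bs <- c(bs, bl$end[i] - (hi - off[i]) + 1L)
      be <- c(be, bl$end[i] - (lo - off[i]))
    }
  }
  blocks <- data.frame(start = as.integer(bs), end = as.integer(be))
  jd <- ja <- jl <- jr <- integer(0)
  if (nrow(blocks) > 1L) {
    blens <- blocks$end - blocks$start + 1L
    tot <- sum(blens)
    for (i in seq_len(nrow(blocks) - 1L)) {
      upstream_nt <- sum(blens[seq_len(i)])       # transcript-side 5' of junction
      if (model$strand == "+") {
        jd <- c(jd, blocks$end[i]); ja <- c(ja, blocks$start[i + 1L])
        jl <- c(jl, upstream_nt); jr <- c(jr, tot - upstream_nt)
      } else {
        jd <- c(jd, blocks$end[i + 1L]); ja <- c(ja, blocks$start[i])
        jl <- c(jl, tot - upstream_nt); jr <- c(jr, upstream_nt)
      }
    }
  }
  junc <- data.frame(donor = jd, acceptor = ja, lnt = jl, rnt = jr)
  structure(list(blocks = blocks, junctions = junc, strand = model$strand,
                 chrom = model$chrom, isoform = isoform,
                 aa_start = aa_start, aa_end = aa_end),
            class = "peptide_alignment")
}

#' Junction support from projected peptides
#'
#' A peptide supports a junction iff its genomic blocks cross it with at
#' least `min_flank` nucleotides on each side (default 3 nt, one codon).
#' Per-event proteomic support counts, for every event path, the peptides
#' supporting at least one of the path's junctions; detection status
#' summarises whether one or both alternatives have support.
#'
#' @param alignments list of [project_peptide()] results (one per
#'   evidence peptide).
#' @param graph a [build_graph()] result.
#' @param events optional precomputed [enumerate_events()] table.
#' @param min_flank minimum nucleotides required on each side.
#' @return list: `junctions` (`data.table` `donor`, `acceptor`,
#'   `n_peptides`), `events` (event table plus `support` list-column of
#'   per-path peptide counts, `n_paths_supported`, `detection` in
#'   `{"none","one","both"}`).
#' @export
junction_peptide_support <- function(alignments, graph, events = NULL,
                                     min_flank = 3L) {
  if (is.null(events)) events <- enumerate_events(graph)
  hits <- list()
  for (al in alignments) {
    if (!inherits(al, "peptide_alignment")) stop("alignments must be peptide_alignment objects")
    j <- al$junctions
    if (nrow(j) == 0L) next
    ok <- j$lnt >= min_flank & j$rnt >= min_flank
    if (any(ok))
      hits[[length(hits) + 1L]] <- data.table::data.table(
        donor = j$donor[ok], acceptor = j$acceptor[ok])
  }
  jcount <- if (length(hits)) {
    data.table::rbindlist(hits)[, list(n_peptides = .N), by = list(donor, acceptor)]
  } else data.table::data.table(donor = integer(0), acceptor = integer(0),
                                n_peptides = integer(0))
  support_of <- function(path) {
    keys <- path_junctions(path)
    if (!length(keys)) return(0L)
    parts <- data.table::tstrsplit(keys, ">", fixed = TRUE)
    tot <- 0L
    for (q in seq_along(keys)) {
      m <- jcount[donor == as.integer(parts[[1]][q]) &
                  acceptor == as.integer(parts[[2]][q])]
      if (nrow(m)) tot <- tot + m$n_peptides
    }
    tot
  }
  if (nrow(events)) {
    events <- data.table::copy(events)
    events[, support := lapply(paths, function(ps) vapply(ps, support_of, integer(1)))]
    events[, n_paths_supported := vapply(support, function(s) sum(s > 0L), integer(1))]
    events[, detection := c("none", "one", "both")[pmin(n_paths_supported, 2L) + 1L]]
  }
  list(junctions = jcount[], events = events)
}

# ---- PSI and detection-rate summaries --------------------------------------

#' Percent-spliced-in of cassette events from junction reads
#'
#' PSI is the inclusion fraction: the two inclusion junction read counts
#' are averaged and divided by that average plus the exclusion junction
#' reads. Events with zero total reads get `NA` (undefined, not 0).
#'
#' @param events [enumerate_events()] table (cassette events are
#'   quantified; other types get `NA`).
#' @param junction_reads `data.frame`: `gene_id`, `donor`, `acceptor`,
#'   `reads` (and optionally `rpm`).
#' @return the event table with added `psi` column.
#' @export
psi_from_reads <- function(events, junction_reads) {
  jr <- data.table::as.data.table(junction_reads)
  reads_of <- function(gene, d, a) {
    m <- jr[gene_id == gene & donor == d & acceptor == a]
    if (nrow(m)) sum(m$reads) else 0
  }
  events <- data.table::copy(events)
  psi <- rep(NA_real_, nrow(events))
  for (r in seq_len(nrow(events))) {
    if (events$type[r] != "cassette exon") next
    ps <- events$paths[[r]]
    direct <- which(lengths(ps) == 2L)[1]
    incl <- which(lengths(ps) == 4L)[1]
    if (is.na(direct) || is.na(incl)) next
    jd <- path_junctions(ps[[direct]])
    ji <- path_junctions(ps[[incl]])
    pd <- data.table::tstrsplit(jd, ">", fixed = TRUE)
    pi_ <- data.table::tstrsplit(ji, ">", fixed = TRUE)
    excl_reads <- reads_of(events$gene_id[r], as.integer(pd[[1]][1]),
                           as.integer(pd[[2]][1]))
    incl_reads <- vapply(seq_along(ji), function(q)
      reads_of(events$gene_id[r], as.integer(pi_[[1]][q]),
               as.integer(pi_[[2]][q])), numeric(1))
    mi <- mean(incl_reads)
    tot <- mi + excl_reads
    psi[r] <- if (tot > 0) mi / tot else NA_real_
  }
  events[, psi := psi]
  events[]
}

#' Detection-rate summaries over expression, PSI and frame status
#'
#' Bins events and reports the fraction detected per bin; the standard
#' views are detection rate vs log2 expression (integer bins), vs PSI
#' bin, and split by frame status.
#'
#' @param events `data.frame` with logical `detected` plus the binning
#'   column(s): `abundance` (RPKM-like), `psi`, `frame_preserving`.
#' @param psi_breaks PSI bin edges.
#' @return list of `data.table`s: `by_expression`, `by_psi`, `by_frame`.
#' @export
detection_rate_tables <- function(events,
                                  psi_breaks = seq(0, 1, by = 0.1)) {
  ev <- data.table::as.data.table(events)
  stopifnot("detected" %in% names(ev))
  out <- list()
  if ("abundance" %in% names(ev)) {
    ev2 <- ev[!is.na(abundance) & abundance > 0]
    ev2[, bin := floor(log2(abundance))]
    out$by_expression <- ev2[, list(n = .N, rate = mean(detected)),
                             by = bin][order(bin)]
  }
  if ("psi" %in% names(ev)) {
    ev2 <- ev[!is.na(psi)]
    ev2[, bin := cut(psi, breaks = psi_breaks, include.lowest = TRUE)]
    out$by_psi <- ev2[, list(n = .N, rate = mean(detected)), by = bin][order(bin)]
  }
  if ("frame_preserving" %in% names(ev)) {
    out$by_frame <- ev[, list(n = .N, rate = mean(detected)),
                       by = frame_preserving]
  }
  out
}

#' Junction-class detection curves versus transcriptional coverage
#'
#' @param junctions `data.frame` with `class`, `rpm` and logical
#'   `detected` per junction.
#' @param breaks log2(RPM) bin edges.
#' @return `data.table`: `class`, `bin`, `n`, `rate`.
#' @export
junction_detection_curves <- function(junctions,
                                      breaks = c(-Inf, 0:8, Inf)) {
  j <- data.table::as.data.table(junctions)
  j <- j[rpm > 0]
  j[, bin := cut(log2(rpm), breaks = breaks)]
  j[, list(n = .N, rate = mean(detected)), by = list(class, bin)][order(class, bin)]
}

#' PSI optimum of the two-junction detection model
#'
#' Under equal per-junction detection efficiency the inclusion isoform
#' offers two detectable junctions with signal proportional to `2 * PSI`
#' while the exclusion isoform offers one with signal proportional to
#' `1 - PSI`. The PSI balancing the two signals solves
#' `2 * PSI = 1 - PSI`, i.e. PSI = 1/3. The simulation draws events on a
#' PSI grid, detects each path with probability proportional to its
#' signal, and locates the grid point where the smaller of the two
#' empirical detection rates is largest (the curves' crossing).
#'
#' @param n_events total number of simulated events across the grid.
#' @param efficiency per-unit-signal detection probability (kept < 0.5 so
#'   probabilities stay in range).
#' @param grid PSI grid.
#' @param seed RNG seed.
#' @return list: `analytic` (1/3, from a root solve), `balance_psi`
#'   (simulated crossing of the two empirical rate curves, from a linear
#'   fit of their difference over the grid), `peak_min_psi` (grid point
#'   maximising the smaller empirical rate), `curve` (`data.table` `psi`,
#'   `rate_inclusion`, `rate_exclusion`, `rate_min`, `n`).
#' @export
psi_detection_optimum <- function(n_events = 10000L, efficiency = 0.45,
                                  grid = seq(0.025, 0.975, by = 0.05),
                                  seed = 1L) {
  analytic <- stats::uniroot(function(p) 2 * p - (1 - p), c(1e-9, 1 - 1e-9),
                             tol = 1e-12)$root
  set.seed(seed)
  per <- floor(n_events / length(grid))
  rows <- lapply(grid, function(p) {
    inc <- stats::rbinom(1L, per, min(1, efficiency * 2 * p)) / per
    exc <- stats::rbinom(1L, per, min(1, efficiency * (1 - p))) / per
    data.table::data.table(psi = p, rate_inclusion = inc,
                           rate_exclusion = exc, rate_min = min(inc, exc),
                           n = per)
  })
  curve <- data.table::rbindlist(rows)
  # both rates are linear in PSI under this model, so the crossing of a
  # linear fit of their difference estimates the balance point
  fit <- stats::lm(I(rate_inclusion - rate_exclusion) ~ psi, data = curve)
  balance <- -stats::coef(fit)[[1]] / stats::coef(fit)[[2]]
  list(analytic = analytic, balance_psi = balance,
       peak_min_psi = curve$psi[which.max(curve$rate_min)],
       curve = curve[])
}
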