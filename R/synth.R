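#' Synthetic-data configuration
#'
#' The stated world for the synthetic genome: multi-exon genes with
#' cassette exons at controlled PSI, nonsynonymous SNPs at controlled
#' density and read depth/quality, per-gene transcript abundance, and an
#' abundance-dependent peptide detection model. Distribution parameters
#' are functions `n -> numeric(n)` so the generator stays pluggable;
#' defaults are chosen once to resemble deep RNA-seq/proteomics data
#' (see the methods vignette).
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_len exon length range in nt (drawn as multiples of 3; a
#'   frame-breaking cassette exon gets 1-2 extra nt).
#' @param intron_len intron length range in nt.
#' @param cassette_fraction probability that an internal exon is a
#'   cassette (alternative) exon.
#' @param frame_preserving_fraction probability that a cassette exon
#'   length is a multiple of 3.
#' @param psi_dist function drawing true PSI values.
#' @param snp_rate nonsynonymous SNPs per kb of CDS.
#' @param depth_dist,allele_freq_dist,baseq_dist,mapq_dist functions
#'   drawing per-site read depth, alt-allele fraction and qualities.
#' @param multimap_prob probability a site is flagged multi-mapped.
#' @param abundance_dist function drawing per-gene RPKM-like abundances.
#' @param detect_model list: `intercept`, `slope` (logistic detection in
#'   log2 abundance) and `protease_eff` named offsets per enzyme.
#' @param reads_per_abundance junction-read budget per abundance unit.
#' @param seed RNG seed; a fixed seed makes every output byte-identical.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 50L,
                         exons_per_gene = c(3L, 8L),
                         exon_len = c(30L, 150L),
                         intron_len = c(40L, 200L),
                         cassette_fraction = 0.35,
                         frame_preserving_fraction = 0.5,
                         psi_dist = function(n) stats::runif(n, 0.05, 0.95),
                         snp_rate = 2,
                         depth_dist = function(n) 1L + stats::rnbinom(n, mu = 29, size = 5),
                         allele_freq_dist = function(n) {
                           low <- stats::runif(n) < 0.2
                           ifelse(low, stats::rbeta(n, 1.5, 10), stats::rbeta(n, 8, 8))
                         },
                         baseq_dist = function(n) pmin(41, pmax(2, round(stats::rnorm(n, 30, 8)))),
                         mapq_dist = function(n) pmin(60, pmax(0, round(stats::rnorm(n, 35, 12)))),
                         multimap_prob = 0.02,
                         abundance_dist = function(n) 2^stats::rnorm(n, 3, 2),
                         detect_model = list(intercept = -5.5, slope = 0.8,
                                             protease_eff = c(trypsin = 0.5, LysC = 0,
                                                              LysN = 0, AspN = -0.2,
                                                              GluC = -0.2,
                                                              chymotrypsin = -0.4)),
                         reads_per_abundance = 20,
                         seed = 1L) {
  stopifnot(n_genes >= 1L,
            length(exons_per_gene) == 2L, exons_per_gene[1] <= exons_per_gene[2],
            exons_per_gene[1] >= 1L,
            length(exon_len) == 2L, exon_len[1] <= exon_len[2],
            cassette_fraction >= 0, cassette_fraction <= 1,
            frame_preserving_fraction >= 0, frame_preserving_fraction <= 1)
  if (floor(exon_len[2] / 3) * 3 < max(9L, exon_len[1]))
    stop("exon_len range too small to host codons")
  structure(as.list(environment()), class = "synth_config")
}

NON_STOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

random_cds <- function(n_codons) paste(sample(NON_STOP_CODONS, n_codons,
                                              replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# sample() treats a length-one x as 1:x; this keeps degenerate ranges safe
sample_range <- function(lo, hi, n = 1L)
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

#' Generate a synthetic genome with gene models and ground truth
#'
#' Lays `n_genes` multi-exon genes on one chromosome, both strands
#' represented. Codons are sampled uniformly from the 61 non-stop codons.
#' Every gene has an all-exon inclusion isoform; each cassette exon adds
#' a skip isoform. Frame-preserving skip isoforms are guaranteed
#' stop-free (the CDS is resampled until every junction codon is clean);
#' a frame-breaking skip isoform is truncated at its first downstream
#' stop codon, emulating a premature-termination product, and the
#' truncation is recorded in the model's `cds_trim`.
#'
#' @param cfg a [synth_config()].
#' @return list of class `synth_truth`: `genome` (named character),
#'   `models` (list of [gene_model()]), `isoform_proteins` (named
#'   character), `isoform_weights` (named numeric, PSI-derived relative
#'   abundances within each gene), `gene_abundance` (named numeric,
#'   RPKM-like), `events` (`data.table` of cassette-event truth),
#'   `cfg`.
#' @export
generate_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  spacer <- 100L
  chrom_parts <- character(0)
  offset <- 0L
  models <- list()
  proteins <- character(0)
  weights <- numeric(0)
  abund <- numeric(0)
  event_rows <- list()
  len_lo <- ceiling(max(9L, cfg$exon_len[1]) / 3L)
  len_hi <- floor(cfg$exon_len[2] / 3L)
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("g%03d", g)
    n_ex <- sample_range(cfg$exons_per_gene[1], cfg$exons_per_gene[2])
    lens <- 3L * sample_range(len_lo, len_hi, n_ex)
    internal <- if (n_ex >= 3L) 2:(n_ex - 1L) else integer(0)
    cass <- internal[stats::runif(length(internal)) < cfg$cassette_fraction]
    frame_ok <- stats::runif(length(cass)) < cfg$frame_preserving_fraction
    lens[cass[!frame_ok]] <- lens[cass[!frame_ok]] + sample(1:2, sum(!frame_ok),
                                                            replace = TRUE)
    if (sum(lens) %% 3L != 0L) {                # pad last exon to codon total
      lens[n_ex] <- lens[n_ex] + (3L - sum(lens) %% 3L)
    }
    total <- sum(lens)
    strand <- sample(c("+", "-"), 1L)
    introns <- sample_range(cfg$intron_len[1], cfg$intron_len[2],
                            max(0L, n_ex - 1L))
    # CDS resampled until every frame-preserving skip isoform is stop-free
    exon_off <- cumsum(c(0L, lens))             # transcript offsets of exons
    for (try in 1:200) {
      cds <- random_cds(total %/% 3L)
      ok <- TRUE
      for (ci in seq_along(cass)) {
        if (!frame_ok[ci]) next
        e <- cass[ci]
        skip <- paste0(substr(cds, 1L, exon_off[e]),
                       substr(cds, exon_off[e] + lens[e] + 1L, total))
        if (grepl("*", translate_nt(skip), fixed = TRUE)) { ok <- FALSE; break }
      }
      if (ok) break
      if (try == 200L) stop("could not sample a stop-free CDS for ", gid)
    }
    # genomic layout
    tx_parts <- character(2L * n_ex - 1L)
    for (i in seq_len(n_ex)) {
      tx_parts[2L * i - 1L] <- substr(cds, exon_off[i] + 1L, exon_off[i] + lens[i])
      if (i < n_ex) tx_parts[2L * i] <- random_dna(introns[i])
    }
    tx <- paste(tx_parts, collapse = "")
    glen <- nchar(tx)
    gseq <- if (strand == "+") tx
    else as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
    # transcript-string coordinates of exon i
    tx_start <- cumsum(c(1L, lens[-n_ex] + introns))
    tx_end <- tx_start + lens - 1L
    if (strand == "+") {
      gstart <- offset + tx_start; gend <- offset + tx_end
    } else {
      gstart <- offset + (glen - tx_end) + 1L; gend <- offset + (glen - tx_start) + 1L
    }
    exons <- data.table::data.table(exon_id = sprintf("%se%02d", gid, seq_len(n_ex)),
                                    start = gstart, end = gend)
    # exon ids are numbered in transcript order; on the minus strand that is
    # already descending genomic order, as gene_model() requires
    isoforms <- list()
    isoforms[[paste0(gid, ".t1")]] <- exons$exon_id[seq_len(n_ex)]
    cds_trim <- stats::setNames(integer(0), character(0))
    psi_vals <- cfg$psi_dist(length(cass))
    prot_incl <- translate_nt(cds)
    gene_proteins <- stats::setNames(prot_incl, paste0(gid, ".t1"))
    for (ci in seq_along(cass)) {
      e <- cass[ci]
      iso <- sprintf("%s.t%d", gid, ci + 1L)
      isoforms[[iso]] <- exons$exon_id[setdiff(seq_len(n_ex), e)]
      skip <- paste0(substr(cds, 1L, exon_off[e]),
                     substr(cds, exon_off[e] + lens[e] + 1L, total))
      aa <- translate_nt(skip)
      stop_at <- regexpr("*", aa, fixed = TRUE)
      if (stop_at > 0L) {
        prot <- substr(aa, 1L, stop_at - 1L)
        cds_trim[iso] <- nchar(skip) - 3L * (stop_at - 1L)
      } else {
        prot <- aa
        if (nchar(skip) %% 3L != 0L) cds_trim[iso] <- nchar(skip) %% 3L
      }
      gene_proteins[iso] <- prot
      o1 <- exon_off[e]; o2 <- exon_off[e] + lens[e]
      event_rows[[length(event_rows) + 1L]] <- data.table::data.table(
        event_id = paste0(gid, "_ev", ci),
        gene_id = gid, exon_id = exons$exon_id[e],
        incl_isoform = paste0(gid, ".t1"), skip_isoform = iso,
        psi = psi_vals[ci], frame_preserving = frame_ok[ci],
        exon_len = lens[e], cds_len = total,
        incl_junction_aa = list(c(ceiling(o1 / 3), ceiling(o2 / 3))),
        skip_junction_aa = list(ceiling(o1 / 3)))
    }
    model <- gene_model(gid, "chrS", strand, exons, isoforms, cds_trim)
    models[[gid]] <- model
    proteins <- c(proteins, gene_proteins)
    # PSI-derived isoform weights within the gene
    w <- stats::setNames(numeric(length(isoforms)), names(isoforms))
    if (length(cass)) {
      w[paste0(gid, ".t1")] <- prod(psi_vals)
      for (ci in seq_along(cass))
        w[sprintf("%s.t%d", gid, ci + 1L)] <-
          (1 - psi_vals[ci]) * prod(psi_vals[-ci])
      w <- w / sum(w)
    } else w[] <- 1
    weights <- c(weights, w)
    abund[gid] <- cfg$abundance_dist(1L)
    chrom_parts <- c(chrom_parts, gseq, random_dna(spacer))
    offset <- offset + glen + spacer
  }
  events <- if (length(event_rows)) data.table::rbindlist(event_rows)
  else data.table::data.table(event_id = character(0), gene_id = character(0),
                              exon_id = character(0), incl_isoform = character(0),
                              skip_isoform = character(0), psi = numeric(0),
                              frame_preserving = logical(0), exon_len = integer(0),
                              cds_len = integer(0), incl_junction_aa = list(),
                              skip_junction_aa = list())
  structure(list(genome = c(chrS = paste(chrom_parts, collapse = "")),
                 models = models, isoform_proteins = proteins,
                 isoform_weights = weights, gene_abundance = abund,
                 events = events, cfg = cfg),
            class = "synth_truth")
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> %d genes, %d isoforms, %d cassette events, genome %d nt\n",
              length(x$models), length(x$isoform_proteins), nrow(x$events),
              nchar(x$genome[[1]])))
  invisible(x)
}

#' Simulate a variant pileup with ground truth
#'
#' Draws nonsynonymous coding SNPs at `snp_rate` per kb of CDS on the
#' inclusion isoform of each gene, with per-site depth, alt-allele count
#' (binomial at the drawn allele fraction), base/mapping quality and a
#' multi-mapped flag from the configured distributions. Truth records the
#' protein consequence and whether the site passes the standard filter
#' cascade.
#'
#' @param truth a [generate_gene_models()] result.
#' @param cfg configuration (defaults to `truth$cfg`).
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return list: `pileup` (`data.table` with CHROM, POS, REF, ALT, DEPTH,
#'   ALT_COUNT, BASEQ, MAPQ, MULTIMAPPED), `truth` (`data.table` adding
#'   `gene_id`, `isoform`, `aa_pos`, `ref_aa`, `alt_aa`, `passes`).
#' @export
simulate_variants <- function(truth, cfg = truth$cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  flt <- variant_filter()
  rows <- list()
  for (model in truth$models) {
    iso <- paste0(model$gene_id, ".t1")
    bl <- cds_blocks(model, iso)
    gpos <- unlist(lapply(seq_len(nrow(bl)), function(i)
      if (model$strand == "+") bl$start[i]:bl$end[i] else bl$end[i]:bl$start[i]))
    cds_len <- length(gpos)
    n_var <- stats::rpois(1L, cds_len / 1000 * cfg$snp_rate)
    if (n_var == 0L) next
    tries <- 0L
    placed <- integer(0)
    while (length(placed) < n_var && tries < 50L * n_var) {
      tries <- tries + 1L
      ci <- sample.int(cds_len, 1L)
      if (ci %in% placed) next
      pos <- gpos[ci]
      ref <- substr(truth$genome[[model$chrom]], pos, pos)
      alts <- setdiff(c("A", "C", "G", "T"), ref)
      alts <- sample(alts)
      chosen <- NULL
      for (alt in alts) {
        cons <- variant_consequence(model, iso, truth$genome, pos, ref, alt)
        if (cons$coding && !cons$synonymous && cons$alt_aa != "*") {
          chosen <- c(list(alt = alt), cons); break
        }
      }
      if (is.null(chosen)) next
      placed <- c(placed, ci)
      depth <- max(1L, as.integer(cfg$depth_dist(1L)))
      freq <- cfg$allele_freq_dist(1L)
      # the drawn allele fraction is realised exactly, so constant-frequency
      # configurations give deterministic filter outcomes
      alt_count <- min(depth, as.integer(round(depth * freq)))
      baseq <- cfg$baseq_dist(1L)
      mapq <- cfg$mapq_dist(1L)
      mm <- stats::runif(1L) < cfg$multimap_prob
      passes <- depth >= flt$min_depth && alt_count >= flt$min_alt &&
        alt_count / depth >= flt$min_freq && baseq >= flt$min_baseq &&
        mapq >= flt$min_mapq && !mm
      rows[[length(rows) + 1L]] <- data.table::data.table(
        CHROM = model$chrom, POS = pos, REF = ref, ALT = chosen$alt,
        DEPTH = depth, ALT_COUNT = alt_count, BASEQ = baseq, MAPQ = mapq,
        MULTIMAPPED = mm, gene_id = model$gene_id, isoform = iso,
        aa_pos = chosen$aa_pos, ref_aa = chosen$ref_aa,
        alt_aa = chosen$alt_aa, passes = passes)
    }
  }
  tr <- if (length(rows)) data.table::rbindlist(rows)
  else data.table::data.table(CHROM = character(0), POS = integer(0),
                              REF = character(0), ALT = character(0),
                              DEPTH = integer(0), ALT_COUNT = integer(0),
                              BASEQ = numeric(0), MAPQ = numeric(0),
                              MULTIMAPPED = logical(0), gene_id = character(0),
                              isoform = character(0), aa_pos = integer(0),
                              ref_aa = character(0), alt_aa = character(0),
                              passes = logical(0))
  data.table::setorder(tr, POS)
  pile_cols <- c("CHROM", "POS", "REF", "ALT", "DEPTH", "ALT_COUNT",
                 "BASEQ", "MAPQ", "MULTIMAPPED")
  list(pileup = tr[, pile_cols, with = FALSE], truth = tr[])
}

#' Simulate peptide evidence from digestion and abundance-dependent detection
#'
#' Digests every isoform protein with every protease and retains each
#' in silico peptide with probability
#' `plogis(intercept + slope * log2(isoform_abundance) + protease_eff)`,
#' so inclusion probability is monotone in abundance. Isoform abundance
#' is the gene abundance times the PSI-derived isoform weight.
#'
#' @param truth a [generate_gene_models()] result.
#' @param rules protease rules ([protease_rules()]).
#' @param cfg configuration (defaults to `truth$cfg`).
#' @param params digestion length window.
#' @param always detect every peptide (evidence equals the full digest).
#' @param proteins,abundance optional overrides: a named proteome and
#'   per-protein abundances (e.g. a variant proteome).
#' @param cell_line label recorded on every row.
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return `data.table`: `sequence`, `protein_id`, `start`, `end`,
#'   `protease`, `cell_line`, `psm_count`.
#' @export
simulate_peptide_evidence <- function(truth, rules = protease_rules(),
                                      cfg = truth$cfg,
                                      params = digest_params(),
                                      always = FALSE,
                                      proteins = NULL, abundance = NULL,
                                      cell_line = "synth1",
                                      seed = cfg$seed + 2L) {
  set.seed(seed)
  if (is.null(proteins)) proteins <- truth$isoform_proteins
  if (is.null(abundance)) {
    gene_of <- sub("\\.t[0-9]+$", "", names(proteins))
    abundance <- truth$gene_abundance[gene_of] *
      truth$isoform_weights[names(proteins)]
    names(abundance) <- names(proteins)
  }
  stopifnot(all(names(proteins) %in% names(abundance)))
  dm <- cfg$detect_model
  unknown <- setdiff(names(rules), names(dm$protease_eff))
  if (length(unknown))
    stop("detect model has no efficiency for protease(s): ",
         paste(unknown, collapse = ", "))
  out <- list()
  for (pn in names(rules)) {
    dt <- digest_proteome(proteins, rules[pn], params)
    if (!nrow(dt)) next
    ab <- abundance[dt$protein_id]
    keep <- if (always) rep(TRUE, nrow(dt)) else {
      p <- stats::plogis(dm$intercept + dm$slope * log2(pmax(ab, 1e-9)) +
                           dm$protease_eff[[pn]])
      p[ab <= 0] <- 0
      stats::runif(nrow(dt)) < p
    }
    dt <- dt[keep]
    if (!nrow(dt)) next
    dt[, `:=`(sequence = peptide, cell_line = cell_line,
              psm_count = 1L + stats::rpois(.N, 2))]
    out[[pn]] <- dt[, list(sequence, protein_id, start, end, protease,
                           cell_line, psm_count)]
  }
  if (!length(out))
    return(data.table::data.table(sequence = character(0), protein_id = character(0),
                                  start = integer(0), end = integer(0),
                                  protease = character(0), cell_line = character(0),
                                  psm_count = integer(0)))
  data.table::rbindlist(out)[]
}

#' Simulate junction read counts
#'
#' Each gene gets a junction-read budget proportional to its abundance.
#' For a cassette event the inclusion isoform supports two junctions:
#' inclusion reads are drawn as `Binomial(2N, PSI)` and split evenly
#' between the two inclusion junctions, exclusion reads as
#' `Binomial(N, 1 - PSI)`, so the averaged-inclusion PSI estimator is
#' unbiased. Junctions outside events get reads at the summed weight of
#' the isoforms containing them.
#'
#' @param truth a [generate_gene_models()] result.
#' @param cfg configuration; @param seed RNG seed (default `cfg$seed + 3`).
#' @return `data.table`: `gene_id`, `donor`, `acceptor`, `reads`, `rpm`,
#'   `class` (truth junction class).
#' @export
simulate_junction_reads <- function(truth, cfg = truth$cfg,
                                    seed = cfg$seed + 3L) {
  set.seed(seed)
  rows <- list()
  for (model in truth$models) {
    graph <- build_graph(model)
    events <- enumerate_events(graph)
    jclass <- classify_junctions(graph, events)
    N <- max(1L, round(truth$gene_abundance[[model$gene_id]] *
                         cfg$reads_per_abundance))
    ev_truth <- truth$events[gene_id == model$gene_id]
    reads <- stats::setNames(integer(nrow(jclass)),
                             paste0(jclass$donor, ">", jclass$acceptor))
    handled <- character(0)
    for (r in seq_len(nrow(ev_truth))) {
      skip_iso <- ev_truth$skip_isoform[r]
      incl_paths_j <- path_junctions(graph$paths[[ev_truth$incl_isoform[r]]])
      skip_j <- setdiff(path_junctions(graph$paths[[skip_iso]]), incl_paths_j)
      exon <- model$exons[exon_id == ev_truth$exon_id[r]]
      touches <- function(k) {
        parts <- as.integer(strsplit(k, ">", fixed = TRUE)[[1]])
        parts[1] == exon$end || parts[2] == exon$start
      }
      incl_j <- incl_paths_j[vapply(incl_paths_j, touches, logical(1))]
      psi <- ev_truth$psi[r]
      tot_incl <- stats::rbinom(1L, 2L * N, psi)
      j1 <- stats::rbinom(1L, tot_incl, 0.5)
      incl_counts <- c(j1, tot_incl - j1)
      for (q in seq_along(incl_j))
        if (incl_j[q] %in% names(reads))
          reads[incl_j[q]] <- reads[incl_j[q]] + incl_counts[min(q, 2L)]
      for (k in skip_j)
        if (k %in% names(reads))
          reads[k] <- reads[k] + stats::rbinom(1L, N, 1 - psi)
      handled <- c(handled, incl_j, skip_j)
    }
    rest <- setdiff(names(reads), handled)
    if (length(rest)) {
      iso_w <- truth$isoform_weights[names(model$isoforms)]
      for (k in rest) {
        frac <- sum(iso_w[vapply(names(model$isoforms), function(iso)
          k %in% path_junctions(graph$paths[[iso]]), logical(1))])
        reads[k] <- stats::rbinom(1L, N, min(1, frac))
      }
    }
    rows[[model$gene_id]] <- data.table::data.table(
      gene_id = model$gene_id, donor = jclass$donor,
      acceptor = jclass$acceptor, reads = as.integer(reads),
      class = jclass$class)
  }
  out <- data.table::rbindlist(rows)
  out[, rpm := reads / max(1, sum(reads)) * 1e6]
  out[]
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper: gene models + genome + truth, variant pileup,
#' peptide evidence and junction reads from one configuration.
#'
#' @param cfg a [synth_config()].
#' @param rules protease rules.
#' @return list: `truth`, `pileup`, `variant_truth`, `evidence`,
#'   `junction_reads`.
#' @export
synth_dataset <- function(cfg = synth_config(), rules = protease_rules()) {
  truth <- generate_gene_models(cfg)
  var <- simulate_variants(truth, cfg)
  ev <- simulate_peptide_evidence(truth, rules, cfg)
  jr <- simulate_junction_reads(truth, cfg)
  list(truth = truth, pileup = var$pileup, variant_truth = var$truth,
       evidence = ev, junction_reads = jr)
}

#' Project peptide evidence and score event detection
#'
#' Runs the proteomics side of the splicing analysis on a synthetic
#' dataset: every evidence peptide is projected to genomic coordinates
#' through its source isoform, junction support is accumulated, and each
#' cassette event is scored as detected on one or both paths.
#'
#' @param truth a [generate_gene_models()] result.
#' @param evidence a [simulate_peptide_evidence()] table (start/end are
#'   residue coordinates in the source isoform protein).
#' @param min_flank junction-spanning flank requirement in nt.
#' @return `data.table`: the truth event table plus `n_incl_peptides`,
#'   `n_skip_peptides`, `detected_incl`, `detected_skip`, `detected`
#'   (one path) and `detected_both`.
#' @export
evaluate_event_detection <- function(truth, evidence, min_flank = 3L) {
  ev <- data.table::as.data.table(evidence)
  events <- data.table::copy(truth$events)
  if (!nrow(events)) return(events)
  gene_of <- sub("\\.t[0-9]+$", "", ev$protein_id)
  res <- list()
  for (gid in unique(events$gene_id)) {
    model <- truth$models[[gid]]
    graph <- build_graph(model)
    gev <- ev[gene_of == gid]
    aligns <- lapply(seq_len(nrow(gev)), function(r)
      project_peptide(model, gev$protein_id[r], gev$start[r], gev$end[r]))
    sup <- junction_peptide_support(aligns, graph, min_flank = min_flank)
    jc <- sup$junctions
    count_j <- function(keys) {
      if (!length(keys)) return(0L)
      parts <- strsplit(keys, ">", fixed = TRUE)
      sum(vapply(parts, function(p) {
        m <- jc[donor == as.integer(p[1]) & acceptor == as.integer(p[2])]
        if (nrow(m)) m$n_peptides else 0L
      }, integer(1)))
    }
    et <- events[gene_id == gid]
    for (r in seq_len(nrow(et))) {
      incl_all <- path_junctions(graph$paths[[et$incl_isoform[r]]])
      skip_all <- path_junctions(graph$paths[[et$skip_isoform[r]]])
      exon <- model$exons[exon_id == et$exon_id[r]]
      incl_j <- incl_all[vapply(incl_all, function(k) {
        p <- as.integer(strsplit(k, ">", fixed = TRUE)[[1]])
        p[1] == exon$end || p[2] == exon$start
      }, logical(1))]
      skip_j <- setdiff(skip_all, incl_all)
      et[r, `:=`(n_incl_peptides = count_j(incl_j),
                 n_skip_peptides = count_j(skip_j))]
    }
    res[[gid]] <- et
  }
  out <- data.table::rbindlist(res)
  out[, `:=`(detected_incl = n_incl_peptides > 0L,
             detected_skip = n_skip_peptides > 0L)]
  out[, `:=`(detected = detected_incl | detected_skip,
             detected_both = detected_incl & detected_skip)]
  out[]
}
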