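# two-exon single-isoform gene and a classic cassette gene used throughout
two_exon_gene <- function() {
  gene_model("g2", "chrT", "+",
             data.frame(exon_id = c("e1", "e2"),
                        start = c(1, 101), end = c(30, 160)),
             list(g2.t1 = c("e1", "e2")))
}

cassette_gene <- function(strand = "+", lens = c(30, 45, 60)) {
  start <- c(1, 101, 201)
  exons <- data.frame(exon_id = c("e1", "e2", "e3"),
                      start = start, end = start + lens - 1)
  iso <- list(inc = c("e1", "e2", "e3"), skp = c("e1", "e3"))
  if (strand == "-") iso <- lapply(iso, rev)
  gene_model("gc", "chrT", strand, exons, iso)
}

test_that("build_graph produces the expected node and edge structure", {
  g <- build_graph(two_exon_gene())
  expect_identical(nrow(g$nodes), 4L)
  expect_identical(sum(g$edges$type == "intra"), 2L)
  expect_identical(sum(g$edges$type == "junction"), 1L)
  gc <- build_graph(cassette_gene())
  juncs <- gc$edges[gc$edges$type == "junction", ]
  expect_identical(nrow(juncs), 3L)   # 1-2, 2-3 and 1-3
  # shared boundaries merged: 6 exon-boundary nodes only
  expect_identical(nrow(gc$nodes), 6L)
  # overlapping exons rejected
  expect_error(gene_model("bad", "c", "+",
                          data.frame(exon_id = c("a", "b"),
                                     start = c(1, 20), end = c(30, 50)),
                          list(t1 = c("a", "b"))),
               "overlapping")
})

test_that("isoform paths reconstruct the input isoforms on random graphs", {
  set.seed(41)
  for (i in 1:10) {
    m <- random_gene_model(n_exons = sample(4:6, 1), n_isoforms = sample(2:4, 1))
    g <- build_graph(m)
    for (iso in names(m$isoforms)) {
      ids <- m$isoforms[[iso]]
      e <- m$exons[match(ids, m$exons$exon_id), ]
      e <- e[order(e$start), ]
      want <- as.vector(rbind(paste0("S", e$start), paste0("E", e$end)))
      expect_identical(g$paths[[iso]], want)
    }
  }
})

test_that("enumerate_events classifies canonical topologies", {
  ev <- enumerate_events(build_graph(cassette_gene(lens = c(30, 44, 60))))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$type, "cassette exon")
  expect_identical(ev$delta_nt, 44L)
  expect_false(ev$frame_preserving)
  ev2 <- enumerate_events(build_graph(cassette_gene(lens = c(30, 45 + 3 * 7, 60))))
  expect_identical(ev2$delta_nt, 66L)
  expect_true(ev2$frame_preserving)
  # intron retention: one isoform spans both exons in a single exon
  mir <- gene_model("gi", "chrT", "+",
                    data.frame(exon_id = c("a", "b", "big"),
                               start = c(1, 101, 1), end = c(30, 160, 160)),
                    list(t1 = c("a", "b"), t2 = "big"))
  evi <- enumerate_events(build_graph(mir))
  expect_identical(evi$type, "intron retention")
  # alternative donor on the plus strand
  mad <- gene_model("ga", "chrT", "+",
                    data.frame(exon_id = c("a1", "a2", "b"),
                               start = c(1, 1, 101), end = c(30, 45, 160)),
                    list(t1 = c("a1", "b"), t2 = c("a2", "b")))
  eva <- enumerate_events(build_graph(mad))
  expect_identical(eva$type, "alt 5'")
  # mutually exclusive exons
  mme <- gene_model("gm", "chrT", "+",
                    data.frame(exon_id = c("a", "x", "y", "b"),
                               start = c(1, 101, 151, 301),
                               end = c(30, 130, 180, 360)),
                    list(t1 = c("a", "x", "b"), t2 = c("a", "y", "b")))
  evm <- enumerate_events(build_graph(mme))
  expect_identical(evm$type, "mutually exclusive")
})

test_that("enumerate_events equals exhaustive anchor enumeration on random graphs", {
  set.seed(42)
  for (i in 1:20) {
    m <- random_gene_model(n_exons = sample(4:7, 1), n_isoforms = sample(2:4, 1))
    g <- build_graph(m)
    got <- enumerate_events(g)
    want <- oracle_events(g)
    got_keys <- if (nrow(got)) paste(got$anchor_start, got$anchor_end, sep = "|")
    else character(0)
    expect_setequal(got_keys, names(want))
    for (r in seq_len(nrow(got))) {
      key <- paste(got$anchor_start[r], got$anchor_end[r], sep = "|")
      got_paths <- sort(vapply(got$paths[[r]], paste, character(1),
                               collapse = ","))
      expect_identical(got_paths, want[[key]])
    }
  }
})

test_that("junction classes are total and constitutive iff in all isoforms", {
  set.seed(43)
  for (i in 1:10) {
    m <- random_gene_model(n_exons = sample(4:6, 1), n_isoforms = sample(2:4, 1))
    g <- build_graph(m)
    jc <- classify_junctions(g)
    expect_true(all(jc$class %in% c("constitutive", "inclusion", "exclusion")))
    # brute-force constitutive check
    all_j <- lapply(g$paths, isocover:::path_junctions)
    for (r in seq_len(nrow(jc))) {
      key <- paste0(jc$donor[r], ">", jc$acceptor[r])
      in_all <- all(vapply(all_j, function(p) key %in% p, logical(1)))
      expect_identical(jc$class[r] == "constitutive", in_all)
    }
    # every junction of every isoform got exactly one class
    expect_setequal(unique(unlist(all_j)),
                    paste0(jc$donor, ">", jc$acceptor))
    expect_false(anyDuplicated(paste0(jc$donor, ">", jc$acceptor)) > 0)
  }
})

test_that("peptide projection arithmetic matches hand-worked cases", {
  # single-exon CDS starting at genomic 101, plus strand: aa 1-5 -> 101-115
  m1 <- gene_model("gs", "chrT", "+",
                   data.frame(exon_id = "e", start = 101, end = 220),
                   list(t1 = "e"))
  al <- project_peptide(m1, "t1", 1, 5)
  expect_identical(al$blocks$start, 101L)
  expect_identical(al$blocks$end, 115L)
  expect_identical(nrow(al$junctions), 0L)
  # junction straddle: 4 codons left, 2 right -> blocks of 12 and 6 nt
  m2 <- gene_model("gj", "chrT", "+",
                   data.frame(exon_id = c("e1", "e2"),
                              start = c(1, 101), end = c(12, 160)),
                   list(t1 = c("e1", "e2")))
  al2 <- project_peptide(m2, "t1", 1, 6)
  expect_identical(al2$blocks$end - al2$blocks$start + 1L, c(12L, 6L))
  expect_identical(al2$junctions$donor, 12L)
  expect_identical(al2$junctions$acceptor, 101L)
  expect_identical(al2$junctions$lnt, 12L)
  expect_identical(al2$junctions$rnt, 6L)
  # block lengths always sum to 3x peptide length
  expect_identical(sum(al2$blocks$end - al2$blocks$start + 1L), 18L)
  # beyond the CDS -> error
  expect_error(project_peptide(m2, "t1", 20, 30), "beyond")
})

test_that("projection round-trips through the genome for synthetic peptides", {
  ds <- shared_synth()
  tr <- ds$truth
  ev <- ds$evidence
  revcomp <- function(p) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(p, "")[[1]]), collapse = ""))
  idx <- seq_len(nrow(ev))
  ok <- vapply(idx, function(r) {
    pid <- ev$protein_id[r]
    gid <- sub("\\.t[0-9]+$", "", pid)
    al <- project_peptide(tr$models[[gid]], pid, ev$start[r], ev$end[r])
    pieces <- vapply(seq_len(nrow(al$blocks)), function(i)
      substr(tr$genome[["chrS"]], al$blocks$start[i], al$blocks$end[i]),
      character(1))
    if (al$strand == "-") pieces <- vapply(pieces, revcomp, character(1))
    identical(isocover:::translate_nt(paste(pieces, collapse = "")),
              ev$sequence[r])
  }, logical(1))
  expect_identical(mean(ok), 1)   # 100% of synthetic peptides
})

test_that("junction support requires the flank and is monotone in it", {
  m2 <- gene_model("gj", "chrT", "+",
                   data.frame(exon_id = c("e1", "e2"),
                              start = c(1, 101), end = c(12, 160)),
                   list(t1 = c("e1", "e2")))
  g <- build_graph(m2)
  inside <- project_peptide(m2, "t1", 5, 10)       # fully inside exon 2
  straddle <- project_peptide(m2, "t1", 3, 6)      # 6 nt left, 6 nt right
  sup <- junction_peptide_support(list(inside, straddle), g)
  expect_identical(sup$junctions$n_peptides, 1L)
  # raising min_flank above the overhang removes the support
  sup2 <- junction_peptide_support(list(inside, straddle), g, min_flank = 7L)
  expect_identical(nrow(sup2$junctions), 0L)
  counts <- vapply(c(1L, 3L, 6L, 7L), function(f)
    sum(junction_peptide_support(list(straddle), g,
                                 min_flank = f)$junctions$n_peptides),
    integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("PSI follows its definition on fixed junction reads", {
  m <- cassette_gene(lens = c(30, 45, 60))
  g <- build_graph(m)
  ev <- enumerate_events(g)
  jr <- data.frame(gene_id = "gc",
                   donor = c(30, 145, 30), acceptor = c(101, 201, 201),
                   reads = c(10, 10, 10))
  expect_equal(psi_from_reads(ev, jr)$psi, 0.5)
  jr$reads <- c(10, 10, 0)       # no exclusion reads -> PSI 1
  expect_equal(psi_from_reads(ev, jr)$psi, 1)
  jr$reads <- c(0, 0, 0)         # no reads -> undefined
  expect_true(is.na(psi_from_reads(ev, jr)$psi))
})

test_that("simulated junction reads recover true PSI and classes", {
  ds <- shared_synth()
  tr <- ds$truth
  jr <- ds$junction_reads
  # per-event estimated PSI close to truth where the read budget is adequate
  one_event <- names(which(table(tr$events$gene_id) == 1))
  checked <- 0L
  for (gid in one_event) {
    if (tr$gene_abundance[[gid]] * tr$cfg$reads_per_abundance < 100) next
    g <- build_graph(tr$models[[gid]])
    ev <- psi_from_reads(enumerate_events(g), jr)
    ev <- ev[ev$type == "cassette exon", ]
    truth_psi <- tr$events[tr$events$gene_id == gid, ]
    if (nrow(ev) != 1L) next
    expect_lt(abs(ev$psi - truth_psi$psi), 0.15)
    checked <- checked + 1L
  }
  expect_gt(checked, 2L)
  # inclusion path has exactly twice the junction opportunities
  for (gid in unique(tr$events$gene_id)) {
    g <- build_graph(tr$models[[gid]])
    et <- tr$events[tr$events$gene_id == gid, ]
    for (r in seq_len(nrow(et))) {
      incl <- isocover:::path_junctions(g$paths[[et$incl_isoform[r]]])
      skip <- isocover:::path_junctions(g$paths[[et$skip_isoform[r]]])
      exon <- tr$models[[gid]]$exons[tr$models[[gid]]$exons$exon_id == et$exon_id[r], ]
      incl_j <- incl[vapply(incl, function(k) {
        p <- as.integer(strsplit(k, ">", fixed = TRUE)[[1]])
        p[1] == exon$end || p[2] == exon$start
      }, logical(1))]
      skip_j <- setdiff(skip, incl)
      expect_identical(length(incl_j), 2L * length(skip_j))
    }
  }
})

test_that("the PSI detection optimum sits at one third", {
  res <- psi_detection_optimum(n_events = 10000L, seed = 99L)
  expect_equal(res$analytic, 1 / 3, tolerance = 1e-9)
  expect_gte(res$balance_psi, 0.30)
  expect_lte(res$balance_psi, 0.37)
})

test_that("detection rate increases with abundance on synthetic data", {
  ds <- shared_synth()
  det <- evaluate_event_detection(ds$truth, ds$evidence)
  det$abundance <- ds$truth$gene_abundance[det$gene_id]
  tab <- detection_rate_tables(det)
  expect_true(all(c("by_expression", "by_psi", "by_frame") %in% names(tab)))
  # top abundance quartile detects more events than the bottom quartile
  qs <- stats::quantile(det$abundance, c(0.25, 0.75))
  lo <- mean(det$detected[det$abundance <= qs[1]])
  hi <- mean(det$detected[det$abundance >= qs[2]])
  expect_gt(hi, lo)
})
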