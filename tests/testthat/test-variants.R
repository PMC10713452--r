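make_pileup <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(CHROM = "chrS", POS = seq_len(n),
             REF = sample(c("A", "C", "G", "T"), n, TRUE),
             ALT = sample(c("A", "C", "G", "T"), n, TRUE),
             DEPTH = sample(0:40, n, TRUE),
             ALT_COUNT = 0L, BASEQ = sample(0:41, n, TRUE),
             MAPQ = sample(0:60, n, TRUE),
             MULTIMAPPED = runif(n) < 0.1) |>
    transform(ALT_COUNT = vapply(DEPTH, function(d) sample(0:d, 1), integer(1)))
}

test_that("filter_variants applies the boundary thresholds exactly", {
  row <- function(depth, alt, baseq = 13, mapq = 13, mm = FALSE)
    data.frame(CHROM = "c", POS = 1, REF = "A", ALT = "G", DEPTH = depth,
               ALT_COUNT = alt, BASEQ = baseq, MAPQ = mapq, MULTIMAPPED = mm)
  expect_identical(attr(filter_variants(row(10, 5)), "pass"), TRUE)
  expect_identical(attr(filter_variants(row(9, 9)), "pass"), FALSE)   # depth
  expect_identical(attr(filter_variants(row(40, 5)), "pass"), FALSE)  # freq 12.5%
  expect_identical(attr(filter_variants(row(10, 4)), "pass"), FALSE)  # alt count
  expect_identical(attr(filter_variants(row(10, 5, baseq = 12.9)), "pass"), FALSE)
  expect_identical(attr(filter_variants(row(10, 5, mapq = 12)), "pass"), FALSE)
  expect_identical(attr(filter_variants(row(10, 5, mm = TRUE)), "pass"), FALSE)
  expect_error(filter_variants(row(5, 9)), "malformed")
  expect_error(filter_variants(row(5, 5)[, -5]), "lacks column")
})

test_that("filter pass set equals a per-row predicate oracle on 1000 rows", {
  p <- make_pileup(1000, seed = 31)
  got <- attr(filter_variants(p), "pass")
  want <- vapply(seq_len(nrow(p)), function(r) {
    with(p[r, ], DEPTH >= 10 && ALT_COUNT >= 5 && ALT_COUNT / DEPTH >= 0.15 &&
           BASEQ >= 13 && MAPQ >= 13 && !MULTIMAPPED)
  }, logical(1))
  expect_identical(got, want)
  # row order invariance
  perm <- sample(nrow(p))
  got2 <- attr(filter_variants(p[perm, ]), "pass")
  expect_identical(got2, want[perm])
})

test_that("pass set is monotone when any threshold is relaxed", {
  p <- make_pileup(500, seed = 32)
  base <- attr(filter_variants(p), "pass")
  relaxed <- list(variant_filter(min_depth = 5), variant_filter(min_alt = 2),
                  variant_filter(min_freq = 0.05), variant_filter(min_baseq = 5),
                  variant_filter(min_mapq = 5),
                  variant_filter(drop_multimapped = FALSE))
  for (f in relaxed) {
    r <- attr(filter_variants(p, f), "pass")
    expect_true(all(r[base]))   # relaxing never removes a passing row
  }
})

# A fixed two-gene fixture covering both strands for consequence tests.
# Gene gp (+): single exon, CDS = ATG GAA AAA TGG -> protein MEKW
# Gene gm (-): single exon, CDS = revcomp of genomic
variant_fixture <- function() {
  cds_p <- "ATGGAAAAATGG"
  cds_m <- "ATGTGTCGTTTC"     # protein MCRF
  genome_m <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_m)))
  genome <- c(chrF = paste0(cds_p, "NNNN", genome_m))
  mp <- gene_model("gp", "chrF", "+",
                   data.frame(exon_id = "gpe1", start = 1, end = 12),
                   list(gp.t1 = "gpe1"))
  mm <- gene_model("gm", "chrF", "-",
                   data.frame(exon_id = "gme1", start = 17, end = 28),
                   list(gm.t1 = "gme1"))
  list(genome = genome, models = list(gp = mp, gm = mm))
}

test_that("variant consequences: synonymous, missense, minus strand by hand", {
  fx <- variant_fixture()
  # GAA -> GAG at codon 2: synonymous (E)
  syn <- variant_consequence(fx$models$gp, "gp.t1", fx$genome, 6, "A", "G")
  expect_true(syn$synonymous)
  # GAA -> AAA at codon 2: E2K
  mis <- variant_consequence(fx$models$gp, "gp.t1", fx$genome, 4, "G", "A")
  expect_false(mis$synonymous)
  expect_identical(mis$ref_aa, "E")
  expect_identical(mis$alt_aa, "K")
  expect_identical(mis$aa_pos, 2L)
  # minus strand: CDS codon 2 is TGT (Cys). Genomic pos 23 pairs with CDS
  # pos 6; genomic A->G makes CDS T->C: TGC, still Cys (synonymous)
  cons_m <- variant_consequence(fx$models$gm, "gm.t1", fx$genome, 23, "A", "G")
  expect_true(cons_m$synonymous)
  # genomic C->T at pos 24 is CDS pos 5 G->A: TGT -> TAT = C2Y
  cons_m2 <- variant_consequence(fx$models$gm, "gm.t1", fx$genome, 24, "C", "T")
  expect_false(cons_m2$synonymous)
  expect_identical(cons_m2$ref_aa, "C")
  expect_identical(cons_m2$alt_aa, "Y")
  expect_identical(cons_m2$aa_pos, 2L)
  # outside the CDS
  nc <- variant_consequence(fx$models$gp, "gp.t1", fx$genome, 14, "N", "A")
  expect_false(nc$coding)
})

test_that("build_variant_proteome applies substitutions and skips synonymous", {
  fx <- variant_fixture()
  calls <- data.frame(CHROM = "chrF", POS = c(6, 4, 14),
                      REF = c("A", "G", "N"), ALT = c("G", "A", "A"))
  vp <- build_variant_proteome(fx$models, fx$genome, calls)
  expect_identical(names(vp$proteins), "gp.t1|VAR=E2K")
  expect_identical(unname(vp$proteins[[1]]), "MKKW")
  expect_identical(vp$table$coding, c(TRUE, TRUE, FALSE))
  expect_identical(vp$table$synonymous, c(TRUE, FALSE, NA))
  # round trip: translating the mutated CDS reproduces the mutated protein
  g2 <- fx$genome
  substr(g2[["chrF"]], 4, 4) <- "A"
  cds2 <- extract_cds(fx$models$gp, "gp.t1", g2)
  expect_identical(as.character(Biostrings::translate(
    Biostrings::DNAString(cds2), no.init.codon = TRUE)), "MKKW")
})

test_that("SAP peptide classes follow the Yes/No/Mixed definition", {
  reference <- c(r1 = "AAAAEKWWWW", r2 = "CCCCKKCCCC")
  variant <- c("r1|VAR=E5K" = "AAAAKKWWWW")
  ev <- data.frame(sequence = c("AAAAKKW",   # covers the K5 variant, absent from ref
                                "AAAAEKW",   # reference only
                                "CCCCKKC",   # matches ref r2 AND covers variant in r1? no:
                                "WWWW"))     # shared, no variant coverage
  cls <- classify_sap_peptides(ev, reference, variant)
  st <- stats::setNames(cls$peptides$status, cls$peptides$sequence)
  expect_identical(unname(st["AAAAKKW"]), "Yes")
  expect_identical(unname(st["AAAAEKW"]), "No")
  expect_identical(unname(st["WWWW"]), "No")
  expect_true(cls$saps$detected[cls$saps$entry == "r1|VAR=E5K"])
  # Mixed: variant recreates a sequence present elsewhere in the reference
  reference2 <- c(r1 = "AAAAEKWWWW", r3 = "GGAAAAKKWGG")
  cls2 <- classify_sap_peptides(data.frame(sequence = "AAAAKKW"),
                                reference2, variant)
  expect_identical(cls2$peptides$status, "Mixed")
})

test_that("planted SAPs are detected iff covered by a variant peptide", {
  ds <- shared_synth()
  tr <- ds$truth
  calls <- filter_variants(ds$pileup)
  vp <- build_variant_proteome(tr$models, tr$genome, calls)
  expect_gt(length(vp$proteins), 0L)   # the stated world plants passing SNPs
  # full-detection evidence from the mutated entries
  evm <- simulate_peptide_evidence(tr, proteins = vp$proteins,
                                   abundance = stats::setNames(
                                     rep(1000, length(vp$proteins)),
                                     names(vp$proteins)),
                                   always = TRUE)
  cls <- classify_sap_peptides(evm, tr$isoform_proteins, vp)
  # truth: an entry is detectable iff some digestion peptide covers its residue
  pos_of <- vapply(names(vp$proteins), function(e)
    as.integer(gsub("^.*VAR=[A-Z*]([0-9]+)[A-Z*]$", "\\1", e)), integer(1))
  truth_cov <- vapply(names(vp$proteins), function(e) {
    d <- evm[evm$protein_id == e, ]
    any(d$start <= pos_of[[e]] & d$end >= pos_of[[e]])
  }, logical(1))
  # detected implies covered-by-truth; covered non-detected entries can only
  # arise when the variant peptide also exists in the reference (Mixed)
  got <- stats::setNames(cls$saps$detected, cls$saps$entry)[names(vp$proteins)]
  mixed_seqs <- cls$peptides$sequence[cls$peptides$status == "Mixed"]
  for (e in names(vp$proteins)) {
    if (got[[e]]) expect_true(truth_cov[[e]])
    if (truth_cov[[e]] && !got[[e]]) {
      d <- evm[evm$protein_id == e, ]
      covering <- d$sequence[d$start <= pos_of[[e]] & d$end >= pos_of[[e]]]
      expect_true(all(covering %in% mixed_seqs))
    }
  }
})

test_that("rank-sum test matches exact enumeration for n <= 8 and edge cases", {
  set.seed(33)
  # fixed example
  ex <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  or <- oracle_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ex$statistic, or$W)
  expect_equal(ex$u, 0)
  # random small cases, with ties: statistic equals the enumeration oracle
  for (i in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- sample(1:5, n1, TRUE); y <- sample(1:5, n2, TRUE)
    got <- rank_sum_test(x, y)
    or <- oracle_ranksum(x, y)
    expect_equal(got$statistic, or$W)
  }
  # at moderate n the tie-corrected normal approximation must agree with
  # the reference implementation in stats
  for (i in 1:10) {
    x <- sample(1:20, 30, TRUE); y <- sample(3:22, 25, TRUE)
    got <- rank_sum_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_equal(rank_sum_test(c(1, 1, 1), c(1, 1))$p_value, 1)
  expect_equal(rank_sum_test(1:5, 1:5)$p_value, 1, tolerance = 0.3)
})

test_that("deleteriousness shift detects a planted score shift", {
  set.seed(34)
  detected <- stats::rnorm(500, 0.5, 0.2)
  undetected <- stats::rnorm(500, 0.5 - 0.5 * 0.2, 0.2)
  res <- deleteriousness_shift(detected, undetected)
  expect_lt(res$p_value, 0.01)
  expect_equal(sum(res$fractions$fraction), 2, tolerance = 1e-9)
  # identical lists -> p = 1
  expect_equal(deleteriousness_shift(detected, detected)$p_value, 1,
               tolerance = 0.05)
})
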