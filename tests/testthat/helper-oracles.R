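# Independent brute-force oracles and small fixture builders.

# Digestion oracle: enumerate all substrings and keep those whose
# boundaries are termini or cleavage sites and whose internal site count
# does not exceed max_missed.
oracle_digest <- function(protein, rule, min_len = NULL, max_len = NULL,
                          max_missed = rule$max_missed) {
  n <- nchar(protein)
  sites <- cleavage_sites(protein, rule)
  bounds <- sort(unique(c(0L, sites[sites < n], n)))
  out <- list()
  for (i in 1:n) for (j in i:n) {
    if (!((i - 1L) %in% bounds) || !(j %in% bounds)) next
    internal <- sum(sites > (i - 1L) & sites < j)
    if (internal > max_missed) next
    len <- j - i + 1L
    if (!is.null(min_len) && (len < min_len || len > max_len)) next
    out[[length(out) + 1L]] <- c(i, j, internal)
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      n_missed = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], n_missed = m[, 3])
}

# Coverage oracle: naive sliding-window match marking a boolean array.
oracle_coverage <- function(evidence, proteome) {
  masks <- lapply(proteome, function(s) logical(nchar(s)))
  for (r in seq_len(nrow(evidence))) {
    prot <- proteome[[evidence$protein_id[r]]]
    pep <- evidence$sequence[r]
    np <- nchar(pep); n <- nchar(prot)
    if (np > n) next
    for (i in 1:(n - np + 1L)) {
      if (substr(prot, i, i + np - 1L) == pep)
        masks[[evidence$protein_id[r]]][i:(i + np - 1L)] <- TRUE
    }
  }
  vapply(names(proteome), function(id)
    sum(masks[[id]]) / max(1L, nchar(proteome[[id]])), numeric(1))
}

# Event oracle: a node pair (a, b) is an event anchor iff for some
# isoform pair both contain a and b, the subpaths differ, and no node
# common to that pair lies strictly between a and b.
oracle_events <- function(graph) {
  isos <- names(graph$paths)
  anchors <- list()
  all_nodes <- unique(unlist(graph$paths))
  for (a in all_nodes) for (b in all_nodes) {
    if (a == b) next
    found_paths <- character(0)
    witness <- FALSE
    for (i in seq_along(isos)) for (j in seq_along(isos)) {
      if (i >= j) next
      p1 <- graph$paths[[i]]; p2 <- graph$paths[[j]]
      a1 <- match(a, p1); b1 <- match(b, p1)
      a2 <- match(a, p2); b2 <- match(b, p2)
      if (anyNA(c(a1, b1, a2, b2)) || a1 >= b1 || a2 >= b2) next
      s1 <- p1[a1:b1]; s2 <- p2[a2:b2]
      if (identical(s1, s2)) next
      common <- intersect(s1[-c(1, length(s1))], s2[-c(1, length(s2))])
      if (length(common)) next
      witness <- TRUE
      found_paths <- unique(c(found_paths, paste(s1, collapse = ","),
                              paste(s2, collapse = ",")))
    }
    if (witness)
      anchors[[paste(a, b, sep = "|")]] <- sort(found_paths)
  }
  anchors
}

# Exact rank-sum enumeration for n1 + n2 <= 8: distribution of W over all
# assignments of the observed (mid)ranks to group 1.
oracle_ranksum <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(N, n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(Ws)
  p_exact <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
  list(W = W_obs, p_exact = p_exact, Ws = Ws)
}

# Random gene model with shared first/last exon and random isoform
# subsets of the internal exons.
random_gene_model <- function(gene_id = "gX", n_exons = 5L, n_isoforms = 3L,
                              strand = sample(c("+", "-"), 1L)) {
  lens <- 3L * sample(5:30, n_exons, replace = TRUE)
  gaps <- sample(30:80, n_exons - 1L, replace = TRUE)
  start <- cumsum(c(1L, lens[-n_exons] + gaps))
  exons <- data.frame(exon_id = sprintf("%se%02d", gene_id, 1:n_exons),
                      start = start, end = start + lens - 1L)
  isoforms <- list()
  isoforms[[paste0(gene_id, ".t1")]] <- exons$exon_id
  k <- 2L
  tries <- 0L
  while (length(isoforms) < n_isoforms && tries < 50L) {
    tries <- tries + 1L
    keep <- c(1L, which(runif(n_exons - 2L) > 0.4) + 1L, n_exons)
    keep <- sort(unique(keep))
    ids <- exons$exon_id[keep]
    if (any(vapply(isoforms, identical, logical(1), y = ids))) next
    isoforms[[sprintf("%s.t%d", gene_id, k)]] <- ids
    k <- k + 1L
  }
  ids_by_iso <- lapply(isoforms, function(ids)
    if (strand == "+") ids else rev(ids))
  gene_model(gene_id, "chrT", strand, exons, ids_by_iso)
}

# Small deterministic synthetic dataset shared across tests (built once).
shared_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_dataset(synth_config(n_genes = 40L, seed = 42L))
    cache
  }
})

random_protein <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                    "")[[1]],
                                           n, replace = TRUE), collapse = "")
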