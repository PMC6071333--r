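# Fixture builders and independent oracles shared across the suite.

# minimal gene table: genes laid head-to-tail on one contig
make_genes <- function(families_or_n, contig = "ctg1", symbols = NULL,
                       aa = 300L) {
  n <- if (is.numeric(families_or_n) && length(families_or_n) == 1)
    families_or_n else length(families_or_n)
  width <- 3L * (aa + 1L)
  start <- 1L + (seq_len(n) - 1L) * (width + 50L)
  data.frame(
    gene_id = sprintf("%s_g%02d", contig, seq_len(n)),
    contig_id = contig,
    start = start, end = start + width - 1L,
    strand = "+",
    rank_on_contig = seq_len(n) - 1L,
    protein_length_aa = aa,
    gene_symbols = if (is.null(symbols)) "" else symbols,
    is_full_length = TRUE,
    stringsAsFactors = FALSE
  )
}

make_hit <- function(protein_id, family_id, e_value = 1e-10,
                     bit_score = 100, ali_start = 1L, ali_end = 100L,
                     model_coverage = 0.5) {
  data.frame(protein_id = protein_id, family_id = family_id,
             e_value = e_value, bit_score = bit_score,
             ali_start = as.integer(ali_start),
             ali_end = as.integer(ali_end),
             model_coverage = model_coverage, stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(protein_id = character(), family_id = character(),
             e_value = numeric(), bit_score = numeric(),
             ali_start = integer(), ali_end = integer(),
             model_coverage = numeric(), stringsAsFactors = FALSE)
}

# one passing hit per (gene, family) pairing for a gene table built by
# make_genes(families)
hits_for <- function(genes, families) {
  do.call(rbind, Map(function(pid, fam) make_hit(pid, fam),
                     genes$gene_id, families))
}

# --- independent oracles -------------------------------------------------

# two-sided Fisher p by explicit hypergeometric enumeration over all
# tables with the observed margins
fisher_enum_p <- function(a, total_a, b, total_b) {
  k <- a + b
  xs <- max(0, k - total_b):min(k, total_a)
  probs <- stats::dhyper(xs, total_a, total_b, k)
  p_obs <- probs[match(a, xs)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up applied literally: q_(i) = min_{j>=i} m p_(j)/j
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

# deepest common prefix of lineage strings, token by token
lca_prefix_oracle <- function(lineages) {
  toks <- lapply(lineages, function(s) strsplit(s, ";", fixed = TRUE)[[1]])
  depth <- min(lengths(toks))
  keep <- 0L
  for (d in seq_len(depth)) {
    if (length(unique(vapply(toks, `[`, character(1), d))) == 1L)
      keep <- d else break
  }
  if (keep == 0L) character() else toks[[1]][seq_len(keep)]
}

# gene-id sets of detected PULs, as a canonical sorted list
pul_member_sets <- function(puls) {
  sets <- lapply(strsplit(puls$member_gene_ids, ";", fixed = TRUE), sort)
  sets[order(vapply(sets, paste, character(1), collapse = ","))]
}
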