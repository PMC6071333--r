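# Per-gene helper flags for PUL scanning.  SusD-like variants count as
# SusD; a gene counts as "CAZyme" for locus extension when any retained
# family is GH/CE/PL/CBM/Sus.
.pul_gene_flags <- function(genes, ann) {
  ann <- ann[match(genes$gene_id, ann$protein_id), , drop = FALSE]
  fam_list <- strsplit(ann$families, ";", fixed = TRUE)
  is_susC <- vapply(fam_list, function(f) "SusC" %in% f, logical(1))
  is_susD <- vapply(fam_list, function(f) any(grepl("^SusD", f)), logical(1))
  is_caz <- vapply(fam_list, function(f) {
    if (!length(f) || identical(f, "")) return(FALSE)
    any(family_class(f) %in% c("GH", "CE", "PL", "CBM", "Sus"))
  }, logical(1))
  data.frame(gene_id = genes$gene_id, contig_id = genes$contig_id,
             rank = genes$rank_on_contig, start = genes$start,
             end = genes$end, strand = genes$strand,
             is_susC = is_susC, is_susD = is_susD, is_cazyme = is_caz,
             families = ann$families, stringsAsFactors = FALSE)
}

#' Find tandem SusC-SusD gene pairs on contigs
#'
#' A pair is emitted when a SusC-annotated gene and a SusD-annotated gene
#' (SusD-like variants included) on the same contig are separated by at
#' most `max_pair_gap_genes` intervening genes, in either order.  Each gene
#' participates in at most one pair; pairing is greedy left-to-right in
#' gene-rank order.  Strand is ignored.
#'
#' @param genes gene table.
#' @param ann annotation table ([classify_cazymes()]).
#' @param max_pair_gap_genes intervening genes allowed within a pair
#'   (default 0: strictly adjacent).
#' @return data.frame `contig_id`, `susC_gene_id`, `susD_gene_id`,
#'   `rank_lo`, `rank_hi`.
#' @export
find_sus_pairs <- function(genes, ann, max_pair_gap_genes = 0L) {
  fl <- .pul_gene_flags(genes, ann)
  fl <- fl[order(fl$contig_id, fl$rank), , drop = FALSE]
  out <- list()
  for (ctg in unique(fl$contig_id)) {
    g <- fl[fl$contig_id == ctg, , drop = FALSE]
    used <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      if (used[i]) next
      want <- if (g$is_susC[i]) "is_susD" else if (g$is_susD[i]) "is_susC"
              else next
      jmax <- min(nrow(g), i + max_pair_gap_genes + 1L)
      js <- seq.int(i + 1L, length.out = max(0L, jmax - i))
      js <- js[!used[js] & g[[want]][js]]
      if (!length(js)) next
      j <- js[1]
      used[i] <- used[j] <- TRUE
      susC <- if (g$is_susC[i]) i else j
      susD <- if (susC == i) j else i
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg,
        susC_gene_id = g$gene_id[susC],
        susD_gene_id = g$gene_id[susD],
        rank_lo = min(g$rank[i], g$rank[j]),
        rank_hi = max(g$rank[i], g$rank[j]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(contig_id = character(), susC_gene_id = character(),
                      susD_gene_id = character(), rank_lo = integer(),
                      rank_hi = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Extend one pair outward along the contig.  Returns the member gene-rank
# range: walking out from the pair, a CAZyme gene joins (together with any
# interior genes that were skipped over); extension stops in a direction
# after `window_genes` consecutive non-CAZyme genes.
.extend_ranks <- function(g, rank_lo, rank_hi, window_genes) {
  ranks <- g$rank
  lo <- rank_lo; hi <- rank_hi
  # leftwards
  streak <- 0L
  r <- lo - 1L
  while (r >= min(ranks) && streak < window_genes) {
    i <- match(r, ranks)
    if (g$is_cazyme[i]) { lo <- r; streak <- 0L } else streak <- streak + 1L
    r <- r - 1L
  }
  # rightwards
  streak <- 0L
  r <- hi + 1L
  while (r <= max(ranks) && streak < window_genes) {
    i <- match(r, ranks)
    if (g$is_cazyme[i]) { hi <- r; streak <- 0L } else streak <- streak + 1L
    r <- r + 1L
  }
  c(lo, hi)
}

#' Extend a SusC-SusD pair into a polysaccharide utilization locus
#'
#' Walks outward from the pair in both directions along the contig's gene
#' order.  A gene joins the locus if it is CAZyme-annotated
#' (GH/CE/PL/CBM/Sus) or lies between the pair and a joining gene;
#' extension stops in a direction after `window_genes` consecutive
#' non-CAZyme genes.  Interior non-CAZyme genes are kept and counted in
#' `n_unknown_function`.
#'
#' @param pair one row of [find_sus_pairs()] output.
#' @param genes gene table.
#' @param ann annotation table.
#' @param window_genes stop rule (default 5).
#' @return list of class `pul`: `contig_id`, `member_gene_ids` (in gene
#'   order), `sus_pairs` (data.frame), `cazyme_families` (character),
#'   `span` (c(start, end) bp), `rank_range`, `n_unknown_function`.
#' @export
extend_pul <- function(pair, genes, ann, window_genes = 5L) {
  fl <- .pul_gene_flags(genes, ann)
  g <- fl[fl$contig_id == pair$contig_id, , drop = FALSE]
  g <- g[order(g$rank), , drop = FALSE]
  rr <- .extend_ranks(g, pair$rank_lo, pair$rank_hi, window_genes)
  members <- g[g$rank >= rr[1] & g$rank <= rr[2], , drop = FALSE]
  fams <- unlist(strsplit(members$families[members$is_cazyme], ";",
                          fixed = TRUE))
  structure(list(
    contig_id = pair$contig_id,
    member_gene_ids = members$gene_id,
    sus_pairs = data.frame(susC_gene_id = pair$susC_gene_id,
                           susD_gene_id = pair$susD_gene_id,
                           stringsAsFactors = FALSE),
    cazyme_families = fams,
    span = c(min(members$start), max(members$end)),
    rank_range = rr,
    n_unknown_function = sum(!members$is_cazyme)
  ), class = "pul")
}

#' Merge nearby PULs on one contig
#'
#' PULs whose member-gene ranks are separated by at most `merge_gap_genes`
#' genes are merged (union of members, pairs and families); otherwise they
#' are kept distinct.
#'
#' @param puls list of `pul` objects on one contig, any order.
#' @param merge_gap_genes maximal separation in gene ranks (default 2).
#' @param genes,ann tables used to rebuild merged member lists.
#' @return list of `pul` objects sorted by span.
#' @export
merge_puls <- function(puls, merge_gap_genes = 2L, genes = NULL, ann = NULL) {
  if (!length(puls)) return(puls)
  stopifnot(length(unique(vapply(puls, `[[`, character(1), "contig_id"))) == 1)
  ord <- order(vapply(puls, function(p) p$rank_range[1], numeric(1)))
  puls <- puls[ord]
  merged <- list(puls[[1]])
  for (p in puls[-1]) {
    last <- merged[[length(merged)]]
    if (p$rank_range[1] - last$rank_range[2] - 1L <= merge_gap_genes) {
      last$rank_range <- c(last$rank_range[1],
                           max(last$rank_range[2], p$rank_range[2]))
      last$member_gene_ids <- union(last$member_gene_ids, p$member_gene_ids)
      last$sus_pairs <- unique(rbind(last$sus_pairs, p$sus_pairs))
      last$cazyme_families <- c(last$cazyme_families, p$cazyme_families)
      last$span <- c(min(last$span[1], p$span[1]),
                     max(last$span[2], p$span[2]))
      last$n_unknown_function <- NA_integer_  # recomputed below
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- p
    }
  }
  if (!is.null(genes) && !is.null(ann)) {
    fl <- .pul_gene_flags(genes, ann)
    for (k in seq_along(merged)) {
      p <- merged[[k]]
      g <- fl[fl$contig_id == p$contig_id &
                fl$rank >= p$rank_range[1] & fl$rank <= p$rank_range[2], ,
              drop = FALSE]
      g <- g[order(g$rank), , drop = FALSE]
      p$member_gene_ids <- g$gene_id
      p$cazyme_families <- unlist(strsplit(g$families[g$is_cazyme], ";",
                                           fixed = TRUE))
      p$span <- c(min(g$start), max(g$end))
      p$n_unknown_function <- sum(!g$is_cazyme)
      merged[[k]] <- p
    }
  }
  merged
}

#' Detect polysaccharide utilization loci
#'
#' End-to-end PUL scan: tandem SusC-SusD pairs ([find_sus_pairs()]) are
#' each extended to nearby CAZyme genes ([extend_pul()]) and, by default,
#' loci with nearly adjacent member ranks on a contig are merged
#' ([merge_puls()]) so multi-pair loci (e.g. susC-susD-susC-susD-susE
#' arrangements) are reported once.
#'
#' @param genes gene table.
#' @param ann annotation table.
#' @param bin_map optional data.frame `contig_id`, `bin_id`.
#' @param max_pair_gap_genes see [find_sus_pairs()].
#' @param window_genes see [extend_pul()].
#' @param merge_gap_genes see [merge_puls()].
#' @param merge merge nearby loci (default TRUE); `FALSE` reports each
#'   extended pair as its own locus.
#' @return data.frame with one row per PUL: `pul_id`, `contig_id`,
#'   `bin_id`, `start`, `end`, `n_genes`, `n_sus_pairs`,
#'   `n_unknown_function`, `member_gene_ids` (";"-collapsed),
#'   `cazyme_families` (";"-collapsed multiset); attribute `puls` holds the
#'   list of `pul` objects.
#' @export
detect_puls <- function(genes, ann, bin_map = NULL,
                        max_pair_gap_genes = 0L, window_genes = 5L,
                        merge_gap_genes = 2L, merge = TRUE) {
  pairs <- find_sus_pairs(genes, ann, max_pair_gap_genes)
  all_puls <- list()
  for (ctg in unique(pairs$contig_id)) {
    pr <- pairs[pairs$contig_id == ctg, , drop = FALSE]
    puls <- lapply(seq_len(nrow(pr)), function(i)
      extend_pul(pr[i, ], genes, ann, window_genes))
    if (merge)
      puls <- merge_puls(puls, merge_gap_genes, genes = genes, ann = ann)
    all_puls <- c(all_puls, puls)
  }
  if (!length(all_puls)) {
    out <- data.frame(
      pul_id = character(), contig_id = character(), bin_id = character(),
      start = integer(), end = integer(), n_genes = integer(),
      n_sus_pairs = integer(), n_unknown_function = integer(),
      member_gene_ids = character(), cazyme_families = character(),
      stringsAsFactors = FALSE
    )
    attr(out, "puls") <- list()
    return(out)
  }
  bin_of <- function(ctg) {
    if (is.null(bin_map)) return("unassigned")
    b <- bin_map$bin_id[match(ctg, bin_map$contig_id)]
    if (is.na(b)) "unassigned" else b
  }
  out <- do.call(rbind, lapply(seq_along(all_puls), function(i) {
    p <- all_puls[[i]]
    data.frame(
      pul_id = sprintf("PUL%03d", i),
      contig_id = p$contig_id,
      bin_id = bin_of(p$contig_id),
      start = p$span[1], end = p$span[2],
      n_genes = length(p$member_gene_ids),
      n_sus_pairs = nrow(p$sus_pairs),
      n_unknown_function = p$n_unknown_function,
      member_gene_ids = paste(p$member_gene_ids, collapse = ";"),
      cazyme_families = paste(p$cazyme_families, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "puls") <- all_puls
  out
}

#' Summarize PULs per genome bin
#'
#' @param puls PUL table from [detect_puls()].
#' @param bins bin QC table (all bins listed, including those with zero
#'   PULs).
#' @return list: `per_bin` data.frame (`bin_id`, `n_puls`), `min_puls`,
#'   `max_puls`, `mean_puls` over bins with at least one PUL (all `NA`
#'   when no PUL exists anywhere, with a message).
#' @export
summarize_puls <- function(puls, bins) {
  counts <- stats::setNames(rep(0L, nrow(bins)), bins$bin_id)
  if (nrow(puls)) {
    tab <- table(puls$bin_id[puls$bin_id %in% names(counts)])
    counts[names(tab)] <- as.integer(tab)
  }
  per_bin <- data.frame(bin_id = names(counts), n_puls = unname(counts),
                        stringsAsFactors = FALSE)
  nz <- counts[counts > 0]
  if (!length(nz)) {
    message("no PULs detected in any bin")
    return(list(per_bin = per_bin, min_puls = NA_real_,
                max_puls = NA_real_, mean_puls = NA_real_))
  }
  list(per_bin = per_bin, min_puls = min(nz), max_puls = max(nz),
       mean_puls = mean(nz))
}
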