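#' CAZyme density per megabase of assembled DNA
#'
#' The headline comparability metric across metagenomes: gene count per
#' Mbp of assembly.
#'
#' @param count gene count (>= 0).
#' @param assembled_bp assembled bases (> 0).
#' @return count / (assembled_bp / 1e6), unrounded.
#' @export
#' @examples
#' round(density_per_mbp(31832, 1.26e9), 1)  # 25.3
density_per_mbp <- function(count, assembled_bp) {
  if (!is.numeric(assembled_bp) || assembled_bp <= 0)
    stop("assembled_bp must be > 0")
  count / (assembled_bp / 1e6)
}

#' Counts as percentages of a common denominator
#'
#' @param numerators named integer vector or list (label -> count).
#' @param denominator positive integer.
#' @return data.frame `label`, `count`, `pct` (100 * count / denominator,
#'   unrounded).
#' @export
#' @examples
#' fraction_report(c(full_length = 1536919), 2736491)
fraction_report <- function(numerators, denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  n <- unlist(numerators)
  data.frame(label = names(n), count = unname(n),
             pct = 100 * unname(n) / denominator,
             stringsAsFactors = FALSE)
}

#' Genome-wide CAZyme census
#'
#' Counts proteins by primary class and domain occurrences by family, and
#' derives the density and fraction statistics used for cross-metagenome
#' comparison.  The protein-level census counts each protein once (its
#' primary class); the family table counts distinct protein-family
#' combinations, because family totals are conventionally reported
#' per-sequence-per-family.
#'
#' @param ann annotation table ([classify_cazymes()]); one row per gene of
#'   the dataset (genes without hits carry `primary_class = "none"`).
#' @param genes gene table; defines the ORF universe.
#' @param assembled_bp assembled bases (> 0).
#' @param min_contig_bp if > 0, genes on contigs shorter than this are
#'   excluded before counting (`contigs` must then be supplied).
#' @param contigs contig table, required when `min_contig_bp > 0`.
#' @return list of class `cazyme_census`: `n_orfs_total`,
#'   `n_cazyme_proteins`, `per_class_counts` (named integer),
#'   `per_family_counts`, `n_multidomain`, `assembled_mbp`, `gh_per_mbp`,
#'   `pct_cazyme_of_orfs`, `pct_gh_of_orfs`, `per_class_pct_of_cazymes`,
#'   `n_full_length`, `pct_full_length`, `denominator` (the named ORF
#'   denominator used).
#' @export
cazyme_census <- function(ann, genes, assembled_bp, min_contig_bp = 0,
                          contigs = NULL) {
  if (!is.numeric(assembled_bp) || assembled_bp <= 0)
    stop("assembled_bp must be > 0")
  if (min_contig_bp > 0) {
    if (is.null(contigs))
      stop("contigs table required when min_contig_bp > 0")
    long <- contigs$contig_id[contigs$length_bp >= min_contig_bp]
    genes <- genes[genes$contig_id %in% long, , drop = FALSE]
    ann <- ann[ann$protein_id %in% genes$gene_id, , drop = FALSE]
  }
  caz <- ann[ann$primary_class != "none", , drop = FALSE]
  per_class <- table(factor(caz$primary_class, levels = .class_order))
  per_class <- stats::setNames(as.integer(per_class), names(per_class))
  fam_pairs <- unique(do.call(rbind, lapply(
    seq_len(nrow(caz)),
    function(i) {
      fams <- unique(strsplit(caz$families[i], ";", fixed = TRUE)[[1]])
      if (!length(fams)) return(NULL)
      data.frame(protein_id = caz$protein_id[i], family_id = fams,
                 stringsAsFactors = FALSE)
    })))
  per_family <- if (is.null(fam_pairs)) integer(0) else {
    tab <- table(fam_pairs$family_id)
    stats::setNames(as.integer(tab), names(tab))
  }
  n_orfs <- nrow(genes)
  n_caz <- nrow(caz)
  n_gh <- per_class[["GH"]]
  n_full <- sum(genes$is_full_length)
  structure(list(
    n_orfs_total = n_orfs,
    n_cazyme_proteins = n_caz,
    per_class_counts = per_class,
    per_family_counts = per_family,
    n_multidomain = sum(caz$is_multidomain),
    assembled_mbp = assembled_bp / 1e6,
    gh_per_mbp = density_per_mbp(n_gh, assembled_bp),
    pct_cazyme_of_orfs = if (n_orfs > 0) 100 * n_caz / n_orfs else 0,
    pct_gh_of_orfs = if (n_orfs > 0) 100 * n_gh / n_orfs else 0,
    per_class_pct_of_cazymes =
      if (n_caz > 0) 100 * per_class / n_caz else per_class * 0,
    n_full_length = n_full,
    pct_full_length = if (n_orfs > 0) 100 * n_full / n_orfs else 0,
    denominator = c(orfs = n_orfs)
  ), class = "cazyme_census")
}

#' @export
print.cazyme_census <- function(x, ...) {
  cat("CAZyme census over", x$n_orfs_total, "ORFs:",
      x$n_cazyme_proteins, "CAZyme proteins (",
      sprintf("%.1f%%", x$pct_cazyme_of_orfs), ")\n")
  cat("  GH density:", sprintf("%.1f", x$gh_per_mbp), "per Mbp of",
      sprintf("%.1f", x$assembled_mbp), "Mbp assembled\n")
  cls <- x$per_class_counts[x$per_class_counts > 0]
  if (length(cls))
    cat("  per class:",
        paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
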