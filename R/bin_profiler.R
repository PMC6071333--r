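#' Gate genome bins on completeness and contamination
#'
#' Retains a bin iff `completeness > min_completeness` and
#' `contamination < max_contamination` (both strict, the conventional
#' ">50% complete, <10% contaminated" MAG quality gate).
#'
#' @param bins bin QC table ([read_bin_qc()]).
#' @param min_completeness percent, exclusive lower bound (default 50).
#' @param max_contamination percent, exclusive upper bound (default 10).
#' @return the input with a logical `retained` column appended.
#' @export
qc_gate <- function(bins, min_completeness = 50, max_contamination = 10) {
  bins$retained <- bins$completeness > min_completeness &
    bins$contamination < max_contamination
  bins
}

#' Relative abundance of genome bins from mapped read counts
#'
#' `raw` mode reports the mapped-read fraction,
#' `100 * reads_b / total_reads`.  `per_bp` mode applies a bin-size
#' normalization, scaling each bin's read fraction by
#' `mean(bin size) / size_b` so that coverage-like abundances are
#' comparable across bins of different sizes.
#'
#' @param read_counts data.frame `bin_id`, `mapped_reads`.
#' @param bin_sizes data.frame `bin_id`, `size_bp`.
#' @param total_reads total clean reads (> 0).
#' @param mode `"per_bp"` (default) or `"raw"`.
#' @return data.frame `bin_id`, `abundance_pct`.
#' @export
bin_abundance <- function(read_counts, bin_sizes, total_reads,
                          mode = c("per_bp", "raw")) {
  mode <- match.arg(mode)
  if (total_reads <= 0) stop("total_reads must be > 0")
  sz <- bin_sizes$size_bp[match(read_counts$bin_id, bin_sizes$bin_id)]
  missing_sz <- read_counts$bin_id[is.na(sz) & read_counts$mapped_reads > 0]
  if (length(missing_sz))
    stop("bin(s) with reads but no size: ",
         paste(missing_sz, collapse = ", "))
  frac <- 100 * read_counts$mapped_reads / total_reads
  if (mode == "per_bp") {
    mean_size <- mean(bin_sizes$size_bp)
    frac <- frac * mean_size / sz
    frac[is.na(frac)] <- 0
  }
  data.frame(bin_id = read_counts$bin_id, abundance_pct = frac,
             stringsAsFactors = FALSE)
}

# join gene -> bin via contigs
.gene_bins <- function(genes, bin_map) {
  b <- bin_map$bin_id[match(genes$contig_id, bin_map$contig_id)]
  b[is.na(b)] <- "unassigned"
  b
}

#' Per-bin GH substrate-capability matrix
#'
#' Counts categorized GH proteins per bin per substrate category (the
#' capability-heatmap input), plus a per-family bin count matrix for the
#' full heatmap.
#'
#' @param ann annotation table.
#' @param genes gene table.
#' @param bin_map data.frame `contig_id`, `bin_id`.
#' @param map substrate-category map (default [substrate_categories()]).
#' @return list: `by_category` matrix (bins x categories, incl.
#'   `uncategorized`), `by_family` matrix (bins x GH families).
#' @export
bin_cazyme_matrix <- function(ann, genes, bin_map,
                              map = substrate_categories()) {
  cats <- categorize_gh(ann, map)
  bin_of <- stats::setNames(.gene_bins(genes, bin_map), genes$gene_id)
  bins <- sort(unique(c(bin_map$bin_id, "unassigned")))
  cat_levels <- c(names(map), "uncategorized")
  by_cat <- matrix(0L, nrow = length(bins), ncol = length(cat_levels),
                   dimnames = list(bins, cat_levels))
  fams <- sort(unique(cats$gh_family))
  by_fam <- matrix(0L, nrow = length(bins), ncol = length(fams),
                   dimnames = list(bins, fams))
  if (nrow(cats)) {
    cb <- unname(bin_of[cats$protein_id])
    tab <- table(factor(cb, levels = bins),
                 factor(cats$category, levels = cat_levels))
    by_cat[] <- as.integer(tab)
    tabf <- table(factor(cb, levels = bins),
                  factor(cats$gh_family, levels = fams))
    by_fam[] <- as.integer(tabf)
  }
  list(by_category = by_cat, by_family = by_fam)
}

#' Screen genome bins for cellulosome components
#'
#' Per-bin counts of dockerin-, cohesin- and SLH-carrying proteins,
#' scaffoldin candidates (proteins with >= 2 cohesin domains or a template
#' score call), GH-dockerin fusion proteins, and the list of
#' tandem-cohesin proteins with their domain counts.
#'
#' @param ann annotation table.
#' @param genes gene table.
#' @param bin_map data.frame `contig_id`, `bin_id`.
#' @param scaffoldin_calls optional [call_scaffoldins()] output.
#' @return list: `per_bin` data.frame (`bin_id`, `n_dockerin`,
#'   `n_cohesin`, `n_SLH`, `n_scaffoldin_candidates`,
#'   `gh_dockerin_fusions`), `tandem_cohesins` data.frame (`bin_id`,
#'   `protein_id`, `n_cohesin_domains`).
#' @export
cellulosome_screen <- function(ann, genes, bin_map, scaffoldin_calls = NULL) {
  bin_of <- stats::setNames(.gene_bins(genes, bin_map), genes$gene_id)
  ann$bin_id <- unname(bin_of[ann$protein_id])
  bins <- sort(unique(c(bin_map$bin_id, "unassigned")))
  is_gh_dock <- ann$has_dockerin & vapply(
    strsplit(ann$families, ";", fixed = TRUE),
    function(f) any(family_class(f) == "GH"), logical(1))
  scaff_ids <- unique(c(
    ann$protein_id[ann$n_tandem_cohesins >= 2L],
    if (!is.null(scaffoldin_calls)) scaffoldin_calls$protein_id
  ))
  per_bin <- do.call(rbind, lapply(bins, function(b) {
    a <- ann[!is.na(ann$bin_id) & ann$bin_id == b, , drop = FALSE]
    data.frame(
      bin_id = b,
      n_dockerin = sum(a$has_dockerin),
      n_cohesin = sum(a$has_cohesin),
      n_SLH = sum(a$has_SLH),
      n_scaffoldin_candidates = sum(a$protein_id %in% scaff_ids),
      gh_dockerin_fusions = sum(is_gh_dock[match(a$protein_id,
                                                 ann$protein_id)]),
      stringsAsFactors = FALSE
    )
  }))
  tc <- ann[ann$n_tandem_cohesins >= 2L, , drop = FALSE]
  tandem <- data.frame(bin_id = tc$bin_id, protein_id = tc$protein_id,
                       n_cohesin_domains = tc$n_tandem_cohesins,
                       stringsAsFactors = FALSE)
  rownames(per_bin) <- rownames(tandem) <- NULL
  list(per_bin = per_bin, tandem_cohesins = tandem)
}
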