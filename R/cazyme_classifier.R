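#' Filter HMM domain hits by model coverage and e-value
#'
#' Implements the dbCAN-style two-regime filter: a hit is retained iff its
#' model coverage is at least `coverage_min` and its e-value passes the
#' regime matching its alignment length (`ali_end - ali_start + 1`):
#' alignments longer than `length_threshold` residues use `evalue_long`,
#' alignments of at most `length_threshold` residues use `evalue_short`.
#'
#' @param hits domain-hit table ([read_domain_hits()]).
#' @param coverage_min minimum model coverage (default 0.30).
#' @param evalue_long e-value cutoff for long alignments (default 1e-5).
#' @param evalue_short e-value cutoff for short alignments (default 1e-3).
#' @param length_threshold alignment-length boundary in residues
#'   (default 80; "longer than" is strict).
#' @return the retained rows, same columns as input.
#' @export
#' @examples
#' h <- data.frame(protein_id = "p1", family_id = "GH5", e_value = 1e-6,
#'                 bit_score = 100, ali_start = 1L, ali_end = 100L,
#'                 model_coverage = 0.4)
#' nrow(filter_hits(h))  # 1
filter_hits <- function(hits, coverage_min = 0.30, evalue_long = 1e-5,
                        evalue_short = 1e-3, length_threshold = 80L) {
  if (!nrow(hits)) return(hits)
  aln_len <- hits$ali_end - hits$ali_start + 1L
  e_ok <- ifelse(aln_len > length_threshold,
                 hits$e_value <= evalue_long,
                 hits$e_value <= evalue_short)
  keep <- hits$model_coverage >= coverage_min & e_ok
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping domain hits on each protein
#'
#' Greedy per-protein selection: hits are sorted by e-value ascending, then
#' bit score descending, then family id; a hit is accepted iff its
#' alignment interval shares no residue with any previously accepted hit on
#' that protein.  Non-overlapping hits all survive, which is what permits
#' multi-domain proteins.
#'
#' @param hits filtered domain-hit table.
#' @return the accepted rows, sorted by (protein_id, ali_start).
#' @export
resolve_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$protein_id, hits$e_value, -hits$bit_score,
               hits$family_id, hits$ali_start)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  for (idx in split(seq_len(nrow(hits)), hits$protein_id)) {
    acc_s <- integer(0); acc_e <- integer(0)
    for (i in idx) {
      s <- hits$ali_start[i]; e <- hits$ali_end[i]
      if (!any(s <= acc_e & e >= acc_s)) {
        keep[i] <- TRUE
        acc_s <- c(acc_s, s); acc_e <- c(acc_e, e)
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  out <- out[order(out$protein_id, out$ali_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify proteins into per-protein CAZyme annotations
#'
#' Consumes filtered, overlap-resolved hits.  The primary class of a
#' protein is the class of its retained hit with the lowest e-value
#' (tie-break: higher bit score, then the fixed class order
#' GH < PL < CE < CBM < GT < AA < cellulosome < SLH < Sus).  Cellulosome
#' flags record dockerin/cohesin/SLH presence; `n_tandem_cohesins` counts
#' cohesin hits on the protein.  Genes without any retained hit get
#' `primary_class = "none"`.
#'
#' @param hits filtered + overlap-resolved domain-hit table.
#' @param genes gene table ([read_gene_calls()]); every hit's `protein_id`
#'   must be a known `gene_id`.
#' @return data.frame with one row per gene: `protein_id`, `primary_class`,
#'   `families` (";"-collapsed, in e-value order), `n_domains`,
#'   `is_multidomain` (>= 2 distinct CAZy families), `has_dockerin`,
#'   `has_cohesin`, `n_tandem_cohesins`, `has_SLH`, `best_family`,
#'   `best_gh_family` (best-e-value GH family or NA), `best_e_value`.
#' @export
classify_cazymes <- function(hits, genes) {
  unknown <- setdiff(unique(hits$protein_id), genes$gene_id)
  if (length(unknown))
    stop("domain hits reference unknown protein(s): ",
         paste(unknown, collapse = ", "))
  ann <- data.frame(
    protein_id = genes$gene_id,
    primary_class = "none",
    families = "",
    n_domains = 0L,
    is_multidomain = FALSE,
    has_dockerin = FALSE,
    has_cohesin = FALSE,
    n_tandem_cohesins = 0L,
    has_SLH = FALSE,
    best_family = NA_character_,
    best_gh_family = NA_character_,
    best_e_value = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!nrow(hits)) return(ann)
  cls <- family_class(hits$family_id)
  cls_rank <- match(cls, .class_order)
  ord <- order(hits$protein_id, hits$e_value, -hits$bit_score, cls_rank)
  hits <- hits[ord, , drop = FALSE]
  cls <- cls[ord]
  by_prot <- split(seq_len(nrow(hits)), hits$protein_id)
  for (pid in names(by_prot)) {
    i <- by_prot[[pid]]
    row <- match(pid, ann$protein_id)
    fams <- hits$family_id[i]
    ann$primary_class[row] <- cls[i[1]]
    ann$families[row] <- paste(fams, collapse = ";")
    ann$n_domains[row] <- length(i)
    ann$is_multidomain[row] <- length(unique(fams)) >= 2L
    ann$has_dockerin[row] <- "dockerin" %in% fams
    ann$has_cohesin[row] <- "cohesin" %in% fams
    ann$n_tandem_cohesins[row] <- sum(fams == "cohesin")
    ann$has_SLH[row] <- "SLH" %in% fams
    ann$best_family[row] <- fams[1]
    ann$best_e_value[row] <- hits$e_value[i[1]]
    gh <- fams[cls[i] == "GH"]
    if (length(gh)) ann$best_gh_family[row] <- gh[1]
  }
  ann
}

#' Assign GH-carrying proteins to substrate categories
#'
#' A protein maps to the category of its best-e-value GH family; proteins
#' whose best GH family is in no category are `"uncategorized"`; proteins
#' without a GH hit are dropped.
#'
#' @param ann annotation table ([classify_cazymes()]).
#' @param map substrate-category map (default [substrate_categories()]).
#' @return data.frame `protein_id`, `gh_family`, `category`.
#' @export
categorize_gh <- function(ann, map = substrate_categories()) {
  .check_category_map(map)
  gh <- ann[!is.na(ann$best_gh_family), , drop = FALSE]
  fam2cat <- rep(names(map), lengths(map))
  names(fam2cat) <- unlist(map, use.names = FALSE)
  cat <- unname(fam2cat[gh$best_gh_family])
  cat[is.na(cat)] <- "uncategorized"
  data.frame(protein_id = gh$protein_id, gh_family = gh$best_gh_family,
             category = cat, stringsAsFactors = FALSE)
}

#' Call candidate cellulosomal scaffoldins
#'
#' Two modes of evidence, reported as a union: `score_cutoff` — the
#' protein's best iterative-search template score reaches `score_threshold`
#' (the conventional scaffoldin screen, cutoff 700); `multi_cohesin` — the
#' protein carries at least two cohesin domains, the structural hallmark of
#' a scaffoldin.
#'
#' @param ann annotation table ([classify_cazymes()]).
#' @param template_scores optional data.frame `protein_id`, `template_id`,
#'   `score` (best template similarity score per protein).
#' @param score_threshold minimum template score (default 700, inclusive).
#' @return data.frame `protein_id`, `mode`, `evidence`, `template_id`.
#' @export
call_scaffoldins <- function(ann, template_scores = NULL,
                             score_threshold = 700) {
  calls <- list()
  if (!is.null(template_scores) && nrow(template_scores)) {
    ts <- template_scores[order(template_scores$protein_id,
                                -template_scores$score), , drop = FALSE]
    ts <- ts[!duplicated(ts$protein_id), , drop = FALSE]
    ts <- ts[ts$score >= score_threshold, , drop = FALSE]
    if (nrow(ts))
      calls$score <- data.frame(
        protein_id = ts$protein_id, mode = "score_cutoff",
        evidence = ts$score, template_id = ts$template_id,
        stringsAsFactors = FALSE
      )
  }
  mc <- ann[ann$n_tandem_cohesins >= 2L, , drop = FALSE]
  if (nrow(mc))
    calls$cohesin <- data.frame(
      protein_id = mc$protein_id, mode = "multi_cohesin",
      evidence = as.numeric(mc$n_tandem_cohesins),
      template_id = NA_character_, stringsAsFactors = FALSE
    )
  if (!length(calls))
    return(data.frame(protein_id = character(), mode = character(),
                      evidence = numeric(), template_id = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(out$protein_id, out$mode), , drop = FALSE]
  rownames(out) <- NULL
  out
}
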