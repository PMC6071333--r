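.lineage_ranks <- c("superkingdom", "phylum", "class", "order",
                    "family", "genus", "species")

#' Parse a semicolon-delimited `rank:name` lineage string
#'
#' @param lineage character scalar, e.g.
#'   `"superkingdom:Bacteria;phylum:Bacteroidetes;genus:Prevotella"`.
#' @return data.frame `rank`, `taxon`, ordered superkingdom to species.
#' @export
parse_lineage <- function(lineage) {
  if (is.na(lineage) || !nzchar(lineage))
    return(data.frame(rank = character(), taxon = character(),
                      stringsAsFactors = FALSE))
  toks <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- strsplit(toks, ":", fixed = TRUE)
  df <- data.frame(
    rank = vapply(parts, `[`, character(1), 1),
    taxon = vapply(parts, function(x) paste(x[-1], collapse = ":"),
                   character(1)),
    stringsAsFactors = FALSE
  )
  ord <- match(df$rank, .lineage_ranks)
  if (anyNA(ord)) stop("unknown lineage rank: ",
                       paste(df$rank[is.na(ord)], collapse = ", "))
  if (is.unsorted(ord, strictly = TRUE))
    stop("lineage ranks must be strictly ordered superkingdom -> species")
  df
}

# deepest common prefix over a list of lineage data.frames
.common_prefix <- function(lineages) {
  if (!length(lineages))
    return(data.frame(rank = character(), taxon = character(),
                      stringsAsFactors = FALSE))
  depth <- min(vapply(lineages, nrow, integer(1)))
  keep <- 0L
  for (d in seq_len(depth)) {
    taxa <- vapply(lineages, function(l) l$taxon[d], character(1))
    ranks <- vapply(lineages, function(l) l$rank[d], character(1))
    if (length(unique(taxa)) == 1L && length(unique(ranks)) == 1L)
      keep <- d
    else break
  }
  lineages[[1]][seq_len(keep), , drop = FALSE]
}

#' Lowest-common-ancestor taxonomy for one protein
#'
#' MEGAN-style assignment: of the similarity hits (already screened at
#' e-value <= 1e-3 and capped per protein), retain those with
#' `bit_score >= (1 - top_percent/100) * best bit_score`, then assign the
#' deepest rank at which all retained lineages agree.  Fewer than
#' `min_hits` hits (or none) leaves the protein unassigned.
#'
#' @param hits similarity-hit rows for one protein
#'   ([read_similarity_hits()] columns).
#' @param top_percent bit-score window below the best hit (default 10;
#'   100 = pure LCA over all hits).
#' @param min_hits minimum retained hits for an assignment (default 1).
#' @return list of class `taxon_assignment`: `protein_id`, `lineage`
#'   (data.frame `rank`, `taxon`), `assigned_rank` (or `"unassigned"`),
#'   `assigned_taxon`.
#' @export
lca <- function(hits, top_percent = 10, min_hits = 1L) {
  pid <- if (nrow(hits)) hits$protein_id[1] else NA_character_
  empty <- function() structure(
    list(protein_id = pid,
         lineage = data.frame(rank = character(), taxon = character(),
                              stringsAsFactors = FALSE),
         assigned_rank = "unassigned", assigned_taxon = NA_character_),
    class = "taxon_assignment")
  if (!nrow(hits)) return(empty())
  best <- max(hits$bit_score)
  kept <- hits[hits$bit_score >= (1 - top_percent / 100) * best, ,
               drop = FALSE]
  if (nrow(kept) < min_hits) return(empty())
  lin <- .common_prefix(lapply(kept$lineage, parse_lineage))
  if (!nrow(lin)) return(empty())
  structure(list(
    protein_id = pid,
    lineage = lin,
    assigned_rank = lin$rank[nrow(lin)],
    assigned_taxon = lin$taxon[nrow(lin)]
  ), class = "taxon_assignment")
}

#' Lowest-common-ancestor assignment for all proteins in a hit table
#'
#' @param hits similarity-hit table ([read_similarity_hits()]).
#' @param top_percent,min_hits see [lca()].
#' @return data.frame `protein_id`, `assigned_rank`, `assigned_taxon`,
#'   `lineage` (";"-collapsed `rank:name`), one row per protein present in
#'   `hits`.
#' @export
lca_assign <- function(hits, top_percent = 10, min_hits = 1L) {
  by_prot <- split(hits, hits$protein_id)
  out <- do.call(rbind, lapply(by_prot, function(h) {
    a <- lca(h, top_percent, min_hits)
    data.frame(
      protein_id = a$protein_id,
      assigned_rank = a$assigned_rank,
      assigned_taxon = a$assigned_taxon,
      lineage = paste(paste(a$lineage$rank, a$lineage$taxon, sep = ":"),
                      collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(out))
    out <- data.frame(protein_id = character(), assigned_rank = character(),
                      assigned_taxon = character(), lineage = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# taxon of an assignment at a given rank, NA if not assigned that deep
.taxon_at_rank <- function(lineage_str, rank) {
  vapply(lineage_str, function(s) {
    l <- parse_lineage(s)
    i <- match(rank, l$rank)
    if (is.na(i)) NA_character_ else l$taxon[i]
  }, character(1), USE.NAMES = FALSE)
}

#' Taxonomic breakdown of CAZyme substrate categories
#'
#' For each substrate category, the percentage of category proteins
#' assigned to each taxon at the requested rank, over proteins assigned at
#' least that deep; the unassigned fraction is reported as its own row.
#'
#' @param assignments [lca_assign()] output.
#' @param ann annotation table ([classify_cazymes()]).
#' @param map substrate-category map (default [substrate_categories()]).
#' @param rank `"phylum"` or `"family"`.
#' @return data.frame `category`, `taxon` (`"unassigned"` row included),
#'   `n`, `pct` (of the category's proteins).
#' @export
taxon_breakdown <- function(assignments, ann, map = substrate_categories(),
                            rank = c("phylum", "family")) {
  rank <- match.arg(rank)
  cats <- categorize_gh(ann, map)
  if (!nrow(cats)) {
    message("no categorized proteins to break down")
    return(data.frame(category = character(), taxon = character(),
                      n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  tax <- .taxon_at_rank(
    assignments$lineage[match(cats$protein_id, assignments$protein_id)],
    rank)
  tax[is.na(tax)] <- "unassigned"
  out <- do.call(rbind, lapply(unique(cats$category), function(cc) {
    t <- tax[cats$category == cc]
    tab <- table(t)
    data.frame(category = cc, taxon = names(tab), n = as.integer(tab),
               pct = 100 * as.integer(tab) / length(t),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
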