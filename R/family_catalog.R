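#' Controlled vocabulary of CAZy and accessory domain families
#'
#' The domain-hit readers validate `family_id` against this catalog.  It
#' covers the numbered CAZy classes (GH, GT, CE, PL, CBM, AA) up to generous
#' upper bounds, plus the accessory domains used in cellulosome and
#' polysaccharide-utilization-locus (PUL) analysis: dockerin, cohesin, the
#' S-layer homology domain (SLH), and the starch-utilization-system
#' transporter/binding pair SusC/SusD with its SusD-like variants.
#'
#' @param extra character vector of additional family ids to accept.
#' @return character vector of valid family ids.
#' @export
#' @examples
#' "GH5" %in% cazy_family_catalog()
cazy_family_catalog <- function(extra = character()) {
  c(
    paste0("GH", 1:180),
    paste0("GT", 1:120),
    paste0("CE", 1:20),
    paste0("PL", 1:45),
    paste0("CBM", 1:95),
    paste0("AA", 1:17),
    "dockerin", "cohesin", "SLH",
    "SusC", "SusD", "SusD-like", "SusD-like_2", "SusD-like_3",
    as.character(extra)
  )
}

#' Map family ids to CAZyme classes
#'
#' Classes are `GH`, `GT`, `CE`, `PL`, `CBM`, `AA`, `cellulosome`
#' (dockerin/cohesin), `SLH` and `Sus` (SusC/SusD and SusD-like variants).
#' Unrecognised ids map to `NA`.
#'
#' @param family_id character vector of family ids.
#' @return character vector of class labels, same length as `family_id`.
#' @export
#' @examples
#' family_class(c("GH5", "CBM6", "dockerin", "SusD-like_2"))
family_class <- function(family_id) {
  cls <- rep(NA_character_, length(family_id))
  cls[grepl("^GH[0-9]+$", family_id)]  <- "GH"
  cls[grepl("^GT[0-9]+$", family_id)]  <- "GT"
  cls[grepl("^CE[0-9]+$", family_id)]  <- "CE"
  cls[grepl("^PL[0-9]+$", family_id)]  <- "PL"
  cls[grepl("^CBM[0-9]+$", family_id)] <- "CBM"
  cls[grepl("^AA[0-9]+$", family_id)]  <- "AA"
  cls[family_id %in% c("dockerin", "cohesin")] <- "cellulosome"
  cls[family_id == "SLH"] <- "SLH"
  cls[family_id == "SusC" | grepl("^SusD", family_id)] <- "Sus"
  cls
}

# tie-break order used when a protein's best hits share an e-value and score
.class_order <- c("GH", "PL", "CE", "CBM", "GT", "AA", "cellulosome", "SLH", "Sus")

#' Default substrate-category map for glycoside hydrolases
#'
#' Groups GH families by main substrate and mode of action, the scheme used
#' for lignocellulose-capability profiling: cellulases (endo/exoglucanases),
#' endohemicellulases (xylanases, mannanases, polygalacturonases),
#' debranching enzymes acting on carbohydrate side chains, and
#' oligosaccharide degrading enzymes.
#'
#' @return named list of character vectors (category -> GH family ids);
#'   categories are pairwise disjoint.
#' @export
#' @examples
#' substrate_categories()$cellulases
substrate_categories <- function() {
  list(
    cellulases = c("GH5", "GH9", "GH44", "GH45", "GH48", "GH74"),
    endohemicellulases = c("GH8", "GH10", "GH11", "GH12", "GH26", "GH28", "GH53"),
    debranching = c("GH51", "GH54", "GH67", "GH78"),
    oligosaccharide_degrading = c("GH1", "GH2", "GH3", "GH29", "GH35",
                                  "GH38", "GH39", "GH42", "GH43", "GH94")
  )
}

# validate a user-supplied category map: disjoint, GH-only
.check_category_map <- function(map) {
  stopifnot(is.list(map), length(names(map)) == length(map))
  fams <- unlist(map, use.names = FALSE)
  if (anyDuplicated(fams))
    stop("substrate categories must be pairwise disjoint; duplicated: ",
         paste(unique(fams[duplicated(fams)]), collapse = ", "))
  bad <- fams[family_class(fams) != "GH"]
  if (length(bad))
    stop("substrate categories may only contain GH families; offending: ",
         paste(bad, collapse = ", "))
  invisible(map)
}
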