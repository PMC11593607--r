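#' Controlled vocabulary of foods
#'
#' The 16 widely consumed foods covered by the occurrence database: 4
#' animal-based (beef, egg, salmon, cheese) and 12 plant-based (bread, pasta,
#' rice, wheat, maize, potato, cabbage, carrot, apple, peanuts, beans, olive
#' oil). Each food carries its origin, its EAT-Lancet food group and a flag
#' marking membership of the cereal group (wheat, maize, rice), which is the
#' only group for which dry-basis measurements are retained.
#'
#' @return A data.frame with columns `food`, `origin` (`animal`/`plant`),
#'   `food_group` and logical `cereal`.
#' @export
#' @examples
#' food_vocabulary()
food_vocabulary <- function() {
  df <- utils::read.csv(extdata_path("foods.csv"), stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df$cereal <- as.logical(df$cereal)
  df
}

#' Controlled vocabulary of contaminants
#'
#' The 73 analytes tracked by the pipeline with their chemical class:
#' 4 heavy metals, 18 PAHs, 10 pesticides, 29 mycotoxins and 12 heterocyclic
#' aromatic amines (HAAs).
#'
#' @return A data.frame with columns `contaminant`, `chem_class`
#'   (`heavy_metal`, `PAH`, `pesticide`, `mycotoxin`, `HAA`) and `abbrev`.
#' @export
#' @examples
#' table(contaminant_vocabulary()$chem_class)
contaminant_vocabulary <- function() {
  utils::read.csv(extdata_path("contaminants.csv"), stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}

#' Cereal foods retained on a dry-weight basis
#'
#' @return Character vector of the cereal-group foods (wheat, maize, rice).
#' @export
cereal_foods <- function() {
  voc <- food_vocabulary()
  voc$food[voc$cereal]
}

chem_classes <- function() c("heavy_metal", "PAH", "pesticide", "mycotoxin", "HAA")

#' Default congener aggregation maps
#'
#' Mycotoxin congeners reported individually in the literature are summed into
#' single cumulative indicators before exposure calculations: the four
#' enniatins into `ENNs`, the nine ergot alkaloids into `EgTs`, and
#' alternariol plus alternariol methyl ether into `ATs`.
#'
#' @return Named list of character vectors; names are the aggregate labels,
#'   elements the member contaminant names.
#' @export
#' @examples
#' congener_maps()$ENNs
congener_maps <- function() {
  list(
    ENNs = c("enniatin A", "enniatin B", "enniatin A1", "enniatin B1"),
    EgTs = c("ergotamine", "ergotaminine", "ergokryptine", "ergokryptinine",
             "ergonisine", "ergosine", "ergometrine", "ergocornine",
             "ergocristine"),
    ATs  = c("alternariol", "alternariol methyl ether")
  )
}

#' Default proxy-food map
#'
#' Bread and pasta are sparsely covered in occurrence literature; their
#' concentration estimates are borrowed from maize and wheat respectively.
#'
#' @return Named character vector mapping target food to proxy source food.
#' @export
default_proxy_map <- function() {
  c(bread = "maize", pasta = "wheat")
}

#' Regulatory PAH and beta-carboline indicator members
#'
#' `pah4_members()` returns the four EFSA indicator PAHs; `pah8_members()` the
#' eight-PAH indicator set; `beta_carboline_members()` harman and norharman.
#'
#' @return Character vector of contaminant names.
#' @export
pah4_members <- function() {
  c("benzo[a]pyrene", "benz[a]anthracene", "chrysene", "benzo[b]fluoranthene")
}

#' @rdname pah4_members
#' @export
pah8_members <- function() {
  c(pah4_members(),
    "benzo[k]fluoranthene", "dibenz[a,h]anthracene",
    "benzo[g,h,i]perylene", "indeno[1,2,3-cd]pyrene")
}

#' @rdname pah4_members
#' @export
beta_carboline_members <- function() c("harman", "norharman")

# case-insensitive match of names against a vocabulary column;
# returns canonical spellings, NA where unmatched
match_vocab <- function(x, vocab) {
  idx <- match(tolower(trimws(x)), tolower(vocab))
  vocab[idx]
}
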