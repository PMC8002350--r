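#' Controlled vocabulary of metabolite class and subgroup labels
#'
#' Classes mirror the pathway groups used in water-soluble metabolite
#' profiling of cultured cells: proteinogenic amino acids and their
#' derivatives, urea and TCA cycle intermediates, carbohydrates (including
#' glycolytic intermediates), lipid intermediates, pyrimidines, purines,
#' cofactors and the energy-currency nucleotides/redox pairs. Subgroup
#' labels (`essential`, `branched`, `s_containing`) cut across classes.
#'
#' @return Character vector of allowed annotation labels.
#' @export
annotation_vocabulary <- function() {
  c(
    "amino_acid", "amino_acid_derivative", "essential", "branched",
    "s_containing", "urea_cycle", "tca_cycle", "carbohydrate",
    "lipid_intermediate", "pyrimidine", "purine", "cofactor",
    "energy_currency"
  )
}

#' Built-in metabolite catalog with class annotations
#'
#' A long-format annotation table covering the water-soluble metabolites
#' commonly profiled by ZIC-HILIC LC/MS in cultured fibroblasts. One row per
#' (metabolite, class) membership; metabolites belong to every class or
#' subgroup that applies (valine is `amino_acid`, `essential` and
#' `branched`). The catalog is a starting point, not a closed list: user
#' annotation tables read with [read_annotation()] may extend or replace it.
#'
#' @return A tibble with columns `metabolite_id` and `class`.
#' @examples
#' catalog <- metabolite_catalog()
#' subset(catalog, class == "branched")
#' @export
metabolite_catalog <- function() {
  amino_acids <- c(
    "alanine", "arginine", "asparagine", "aspartate", "cysteine",
    "glutamate", "glutamine", "glycine", "histidine", "isoleucine",
    "leucine", "lysine", "methionine", "phenylalanine", "proline",
    "serine", "threonine", "tryptophan", "tyrosine", "valine"
  )
  membership <- list(
    amino_acid = amino_acids,
    essential = c(
      "histidine", "isoleucine", "leucine", "lysine", "methionine",
      "phenylalanine", "threonine", "tryptophan", "valine"
    ),
    branched = c("leucine", "isoleucine", "valine"),
    amino_acid_derivative = c(
      "creatine", "creatinine", "spermidine", "putrescine", "homoserine",
      "homocysteine", "taurine", "carnitine", "choline", "SAM", "SAH",
      "GSH", "GSSG"
    ),
    s_containing = c(
      "methionine", "cysteine", "homocysteine", "taurine", "SAM", "SAH",
      "GSH", "GSSG"
    ),
    urea_cycle = c(
      "arginine", "ornithine", "citrulline", "argininosuccinate", "urea"
    ),
    tca_cycle = c(
      "citrate", "isocitrate", "alpha-ketoglutarate", "succinate",
      "fumarate", "malate", "oxaloacetate"
    ),
    carbohydrate = c(
      "glucose", "hexose-phosphate", "fructose-1,6-bisphosphate",
      "dihydroxyacetone-phosphate", "3-phosphoglycerate",
      "phosphoenolpyruvate", "pyruvate", "lactate", "UDP-glucose"
    ),
    lipid_intermediate = c(
      "acetoacetate", "hydroxybutyrate", "carnitine", "choline",
      "glycerol-3-phosphate", "CoA", "acetyl-CoA"
    ),
    pyrimidine = c(
      "uracil", "uridine", "UMP", "UDP", "UTP", "cytidine", "CMP",
      "thymidine", "UDP-glucose"
    ),
    purine = c(
      "adenine", "adenosine", "AMP", "ADP", "ATP", "guanine", "guanosine",
      "GMP", "GDP", "GTP", "hypoxanthine", "inosine", "xanthine"
    ),
    cofactor = c(
      "NAD", "NADH", "NADP", "NADPH", "FAD", "pantothenate", "thiamine",
      "CoA"
    ),
    energy_currency = c(
      "ATP", "ADP", "AMP", "GTP", "GDP", "NAD", "NADH", "NADP", "NADPH",
      "creatine-phosphate"
    )
  )
  out <- tibble(
    metabolite_id = unlist(membership, use.names = FALSE),
    class = rep(names(membership), lengths(membership))
  )
  arrange(distinct(out), .data$metabolite_id, .data$class)
}

#' Synonym table for metabolite identifiers
#'
#' Metabolite ids are case-sensitive strings; this table maps common
#' synonyms and abbreviations onto the canonical ids used by
#' [metabolite_catalog()].
#'
#' @return A tibble with columns `alias` and `metabolite_id`.
#' @seealso [canonical_metabolite()]
#' @export
metabolite_aliases <- function() {
  tibble::tribble(
    ~alias,                      ~metabolite_id,
    "glutathione disulphide",    "GSSG",
    "glutathione disulfide",     "GSSG",
    "glutathione",               "GSH",
    "S-adenosylmethionine",      "SAM",
    "S-adenosylhomocysteine",    "SAH",
    "S-AdHom",                   "SAH",
    "pantothenic acid",          "pantothenate",
    "2-oxoglutarate",            "alpha-ketoglutarate",
    "beta-hydroxybutyrate",      "hydroxybutyrate",
    "3-hydroxybutyrate",         "hydroxybutyrate",
    "NAD+",                      "NAD",
    "NADP+",                     "NADP",
    "phosphocreatine",           "creatine-phosphate",
    "coenzyme A",                "CoA"
  )
}

#' Resolve metabolite names to canonical catalog ids
#'
#' Names already present in the catalog are returned unchanged; known
#' synonyms are mapped via [metabolite_aliases()]; anything else passes
#' through untouched (ids are an open set).
#'
#' @param x Character vector of metabolite names.
#' @return Character vector of the same length with canonical ids.
#' @examples
#' canonical_metabolite(c("glutathione disulphide", "NAD+", "serine"))
#' @export
canonical_metabolite <- function(x) {
  al <- metabolite_aliases()
  hit <- match(x, al$alias)
  ifelse(is.na(hit), x, al$metabolite_id[hit])
}
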