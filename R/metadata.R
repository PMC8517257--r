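#' Statin ADR variant panel metadata
#'
#' Loads the packaged description of the seven-variant statin ADR panel:
#' gene, alleles, the literature-pinned genetic model (how genotype enters the
#' regression), the protective genotype classes, and a default minor allele
#' frequency used by the simulator. The packaged YAML can be replaced by any
#' file with the same schema, so panels are data rather than code.
#'
#' @param path Path to a variant metadata YAML file. Defaults to the packaged
#'   panel.
#' @return A `data.table` with one row per variant: `rsid`, `gene`, `chrom`,
#'   `pos`, `major_allele`, `minor_allele`, `genetic_model`, `protective`
#'   (list column of genotype classes), `default_maf`, `default_effect`.
#' @examples
#' variant_metadata()[, .(rsid, gene, genetic_model)]
#' @export
variant_metadata <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "variants.yaml", package = "statinpgx")
  }
  raw <- yaml::read_yaml(path)$variants
  dt <- data.table::rbindlist(lapply(raw, function(v) {
    data.table::data.table(
      rsid = v$rsid, gene = v$gene, chrom = as.character(v$chrom),
      pos = as.integer(v$pos),
      major_allele = v$major_allele, minor_allele = v$minor_allele,
      genetic_model = v$genetic_model,
      protective = list(unlist(v$protective)),
      default_maf = as.numeric(v$default_maf),
      default_effect = as.numeric(v$default_effect)
    )
  }))
  stopifnot(
    all(dt$genetic_model %in% c("additive", "dominant", "recessive")),
    all(dt$major_allele != dt$minor_allele)
  )
  dt[]
}

#' Simvastatin-equivalence potency table
#'
#' Potency ratios converting a statin's daily dose (mg) into the simvastatin
#' dose of equal LDL-lowering effect. Packaged as an editable YAML config:
#' equivalence ratios come from external dosing references and must never be
#' hard-coded.
#'
#' @param path Path to a YAML file with a `ratios:` mapping. Defaults to the
#'   packaged table (atorvastatin x2, rosuvastatin x4, pravastatin x0.5,
#'   fluvastatin x0.5).
#' @return Named numeric vector of ratios keyed by statin type.
#' @examples
#' default_equivalence_table()
#' @export
default_equivalence_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "statin_equivalence.yaml",
                        package = "statinpgx")
  }
  ratios <- unlist(yaml::read_yaml(path)$ratios)
  if (is.null(ratios) || any(ratios <= 0)) {
    stop("equivalence table must provide positive ratios", call. = FALSE)
  }
  ratios
}
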