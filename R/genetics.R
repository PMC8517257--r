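# Genotype QC and encodings: MAF, Hardy-Weinberg testing, genetic-model
# encodings, and the two-variant ABCB1/LILRB5 risk score.

# canonical genotype class: alphabetically sorted allele string ("CT", not "TC")
genotype_class <- function(allele1, allele2) {
  out <- ifelse(allele1 <= allele2,
                paste0(allele1, allele2), paste0(allele2, allele1))
  out[is.na(allele1) | is.na(allele2)] <- NA_character_
  out
}

#' Minor allele frequency from genotype calls
#'
#' Minor-allele count over twice the number of non-missing calls; missing
#' calls are excluded (pairwise deletion).
#'
#' @param allele1,allele2 Allele vectors for one variant (NA = missing call).
#' @param minor_allele The minor allele label.
#' @return Frequency in `[0, 1]`.
#' @examples
#' minor_allele_frequency(c("A", "A", "a"), c("A", "a", "a"), "a") # 0.5
#' @export
minor_allele_frequency <- function(allele1, allele2, minor_allele) {
  ok <- !is.na(allele1) & !is.na(allele2)
  if (!any(ok)) stop("no non-missing genotype calls", call. = FALSE)
  sum(allele1[ok] == minor_allele, allele2[ok] == minor_allele) / (2 * sum(ok))
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency,
#' without continuity correction. A Levene-Haldane exact test (conditional
#' on observed allele counts) is available via `method = "exact"`.
#'
#' @param counts Integer triple `(major_hom, het, minor_hom)`.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return `list(statistic =, p_value =)`; for the exact test the statistic
#'   is `NA`. Monomorphic input gives statistic 0 and p = 1 with a warning.
#' @examples
#' hwe_test(c(25, 50, 25)) # exactly HWE: statistic 0, p 1
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (length(counts) != 3L || any(counts < 0) || anyNA(counts)) {
    stop("counts must be a non-negative triple (major_hom, het, minor_hom)",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero", call. = FALSE)
  n_minor <- counts[2] + 2 * counts[3]
  q <- n_minor / (2 * n)
  if (q == 0 || q == 1) {
    warning("monomorphic variant: HWE test undefined, returning p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  if (method == "chisq") {
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    stat <- sum((counts - expected)^2 / expected)
    list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    list(statistic = NA_real_, p_value = hwe_exact_p(counts))
  }
}

# Levene-Haldane exact HWE p-value: sum of probabilities of heterozygote
# counts no more likely than the observed one, conditional on allele counts.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_minor <- counts[2] + 2 * counts[3]
  n_het_obs <- counts[2]
  parity <- n_minor %% 2
  hets <- seq(parity, min(n_minor, 2 * n - n_minor), by = 2)
  log_prob <- vapply(hets, function(h) {
    n_hom_min <- (n_minor - h) / 2
    n_hom_maj <- n - h - n_hom_min
    lgamma(n + 1) - lgamma(n_hom_maj + 1) - lgamma(h + 1) -
      lgamma(n_hom_min + 1) + h * log(2) +
      lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het_obs, hets)]
  min(1, sum(prob[prob <= p_obs + 1e-12]))
}

#' Encode genotype calls under a genetic model
#'
#' Additive: minor-allele count (0/1/2). Dominant: 1 for any minor-allele
#' carrier. Recessive: 1 for minor-allele homozygotes. Missing calls encode
#' as `NA`.
#'
#' @param allele1,allele2 Allele vectors.
#' @param minor_allele Minor (effect) allele label.
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return Numeric vector of codes.
#' @examples
#' encode_genotype("A", "a", "a", "dominant")  # 1
#' encode_genotype("A", "a", "a", "recessive") # 0
#' @export
encode_genotype <- function(allele1, allele2, minor_allele,
                            model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  count <- (allele1 == minor_allele) + (allele2 == minor_allele)
  switch(model,
    additive = as.numeric(count),
    dominant = as.numeric(count >= 1),
    recessive = as.numeric(count == 2)
  )
}

#' Two-variant ABCB1/LILRB5 unweighted risk score
#'
#' Assigns the binary risk-score level from the joint genotype at ABCB1
#' rs1045642 and LILRB5 rs12975366: level 0 (protected) for ABCB1 CC
#' together with LILRB5 CC or CT; level 1 (at risk of poor response) for
#' ABCB1 CT or TT together with LILRB5 TT. The definitions cover 4 of the 9
#' genotype pairs; the remaining discordant pairs are `NA` (excluded from
#' the binary contrast) under `mode = "strict"`, or counted as non-protected
#' level 1 under `mode = "complement"`. Missing calls are always `NA`.
#'
#' @param abcb1,lilrb5 Genotype class strings (allele pairs in any order,
#'   e.g. `"CT"` or `"TC"`).
#' @param mode `"strict"` (default) or `"complement"`.
#' @return Integer vector of levels (0, 1 or `NA`).
#' @examples
#' two_snp_risk_score("CC", "TC") # 0: protected
#' two_snp_risk_score("CT", "TT") # 1: at risk
#' two_snp_risk_score("CT", "TC") # NA under strict mode
#' @export
two_snp_risk_score <- function(abcb1, lilrb5,
                               mode = c("strict", "complement")) {
  mode <- match.arg(mode)
  a <- genotype_class(substr(abcb1, 1, 1), substr(abcb1, 2, 2))
  b <- genotype_class(substr(lilrb5, 1, 1), substr(lilrb5, 2, 2))
  level0 <- a == "CC" & b %in% c("CC", "CT")
  level1 <- a %in% c("CT", "TT") & b == "TT"
  out <- rep(NA_integer_, length(level0))
  out[level0] <- 0L
  out[level1] <- 1L
  if (mode == "complement") out[!level0 & !is.na(a) & !is.na(b)] <- 1L
  out[is.na(a) | is.na(b)] <- NA_integer_
  out
}

#' Per-variant genotype QC summary
#'
#' Computes call counts, minor allele frequency and the Hardy-Weinberg test
#' for each variant in a long genotype table.
#'
#' @param genotypes Table with `patient_id`, `rsid`, `allele1`, `allele2`.
#' @param variants Variant metadata, see [variant_metadata()].
#' @return `data.table` with one row per variant: `rsid`, `gene`,
#'   `n_called`, `maf`, `hwe_chisq`, `hwe_p`.
#' @export
genotype_qc <- function(genotypes, variants = variant_metadata()) {
  gt <- data.table::as.data.table(genotypes)
  gt <- gt[rsid %in% variants$rsid]
  gt[, genotype := genotype_class(allele1, allele2)]
  out <- gt[!is.na(genotype), {
    v <- variants[rsid == .BY$rsid]
    count <- (allele1 == v$minor_allele) + (allele2 == v$minor_allele)
    counts <- c(sum(count == 0L), sum(count == 1L), sum(count == 2L))
    hw <- suppressWarnings(hwe_test(counts))
    list(gene = v$gene, n_called = .N,
         maf = minor_allele_frequency(allele1, allele2, v$minor_allele),
         hwe_chisq = hw$statistic, hwe_p = hw$p_value)
  }, by = rsid]
  out[]
}

#' Attach encoded genetic terms to a phenotype table
#'
#' For each panel variant present in the genotype table, adds a column
#' `enc_<rsid>` encoding the genotype under the variant's pinned genetic
#' model (pairwise deletion: patients missing one variant keep the others).
#' When both risk-score variants are present, also adds `risk_score_level`
#' (see [two_snp_risk_score()]) and `score_protected` (1 = level 0,
#' 0 = level 1, `NA` otherwise) so that a positive coefficient means better
#' response in the protected group.
#'
#' @param phenotypes Phenotype table with `patient_id`.
#' @param genotypes Long genotype table.
#' @param variants Variant metadata.
#' @param score_variants Character pair (ABCB1 rsid, LILRB5 rsid).
#' @param score_mode Risk-score mode, `"strict"` or `"complement"`.
#' @return The phenotype table with encoded columns added.
#' @export
add_genetic_terms <- function(phenotypes, genotypes,
                              variants = variant_metadata(),
                              score_variants = c("rs1045642", "rs12975366"),
                              score_mode = "strict") {
  ph <- data.table::as.data.table(phenotypes)
  gt <- data.table::as.data.table(genotypes)
  present <- intersect(variants$rsid, unique(gt$rsid))
  for (rs in present) {
    v <- variants[rsid == rs]
    enc_dt <- gt[rsid == rs,
                 .(patient_id,
                   value = encode_genotype(allele1, allele2, v$minor_allele,
                                           v$genetic_model))]
    ph[enc_dt, on = "patient_id", paste0("enc_", rs) := i.value]
  }
  if (all(score_variants %in% present)) {
    a <- gt[rsid == score_variants[1]]
    b <- gt[rsid == score_variants[2]]
    pair <- merge(a[, .(patient_id, ga = genotype_class(allele1, allele2))],
                  b[, .(patient_id, gb = genotype_class(allele1, allele2))],
                  by = "patient_id")
    pair[, level := two_snp_risk_score(ga, gb, mode = score_mode)]
    ph[pair, on = "patient_id", risk_score_level := i.level]
    ph[, score_protected := 1L - risk_score_level]
  }
  ph[]
}

# ---- genotype I/O -----------------------------------------------------------

#' Read genotype calls from CSV or minimal VCF
#'
#' CSV input must have columns `patient_id`, `rsid`, `allele1`, `allele2`.
#' VCF input (`.vcf`) is parsed with the vcfR package; only the GT field is
#' used, and allele indices are resolved against REF/ALT.
#'
#' @param path File path; format chosen by extension.
#' @return Long `data.table` of calls.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(read_genotypes_vcf(path))
  }
  gt <- data.table::fread(path)
  cols <- c("patient_id", "rsid", "allele1", "allele2")
  miss <- setdiff(cols, names(gt))
  if (length(miss)) stop("genotype CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  gt[, (cols) := lapply(.SD, as.character), .SDcols = cols]
  gt[]
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF genotypes requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  out <- data.table::rbindlist(lapply(seq_len(nrow(gt)), function(i) {
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1]])
    calls <- gt[i, ]
    idx <- strsplit(gsub("\\|", "/", calls), "/")
    data.table::data.table(
      patient_id = colnames(gt),
      rsid = fix[i, "ID"],
      allele1 = vapply(idx, function(g)
        if (length(g) < 1 || is.na(g[1]) || g[1] == ".") NA_character_
        else alleles[as.integer(g[1]) + 1L], character(1)),
      allele2 = vapply(idx, function(g)
        if (length(g) < 2 || is.na(g[2]) || g[2] == ".") NA_character_
        else alleles[as.integer(g[2]) + 1L], character(1))
    )
  }))
  out[]
}

#' Write genotype calls as a minimal VCF 4.2
#'
#' Emits CHROM/POS/ID/REF/ALT plus a GT FORMAT column per patient. REF is
#' the panel's major allele. Missing calls become `./.`.
#'
#' @param genotypes Long genotype table.
#' @param path Output path.
#' @param variants Variant metadata providing CHROM/POS/alleles.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(genotypes, path,
                                variants = variant_metadata()) {
  gt <- data.table::as.data.table(genotypes)
  samples <- sort(unique(gt$patient_id))
  rsids <- intersect(variants$rsid, unique(gt$rsid))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(rsids, function(rs) {
    v <- variants[rsid == rs]
    calls <- gt[rsid == rs][match(samples, patient_id)]
    code <- function(a) data.table::fifelse(
      is.na(a), ".", data.table::fifelse(a == v$major_allele, "0", "1"))
    gt_str <- paste(code(calls$allele1), code(calls$allele2), sep = "/")
    gt_str[is.na(calls$allele1) & is.na(calls$allele2)] <- "./."
    paste(c(v$chrom, v$pos, rs, v$major_allele, v$minor_allele, ".", "PASS",
            ".", "GT", gt_str), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
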