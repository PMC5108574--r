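#' Potential inhibitory HLA:KIR interactions of a ligand diplotype
#'
#' A C1/C2 heterozygote presents both inhibitory ligand groups and so can
#' engage up to two distinct inhibitory receptors; a group homozygote can
#' engage only one.
#'
#' @param diplotype A `ligand_diplotype`.
#' @return 1 or 2.
#' @export
potential_inhibitory <- function(diplotype) {
  stopifnot(inherits(diplotype, "ligand_diplotype"))
  if (length(unique(diplotype$c_groups)) == 2) 2L else 1L
}

#' Score HLA:KIR engagements for one subject
#'
#' Applies the ligand/receptor rule matrix: a rule fires when the subject
#' carries the ligand group (C1/C2 from the diplotype; Bw4 when
#' `bw4_count >= 1`) and at least one of the subject's haplotype motifs
#' carries the receptor gene. Each (ligand group, gene) rule fires at most
#' once per subject — interaction types are counted, not gene-dose
#' products — unless `dose_weighted = TRUE`, which multiplies each firing
#' by the number of ligand copies presented (for sensitivity analyses).
#'
#' @param diplotype A `ligand_diplotype`.
#' @param haplotypes Character vector of the subject's haplotype motif
#'   names (centromeric and/or telomeric, e.g. `c("cB01", "tA01")`).
#' @param ref A `kir_reference` bundle.
#' @param dose_weighted Weight engagements by ligand copy number?
#' @return A list of class `interaction_profile`: `subject_id`,
#'   `engagements` (data.frame ligand_group/kir_gene/mode/haplotype),
#'   `n_activating`, `n_inhibitory`, `potential_inhibitory`.
#' @export
interactions_for <- function(diplotype, haplotypes, ref = load_reference(),
                             dose_weighted = FALSE) {
  stopifnot(inherits(diplotype, "ligand_diplotype"))
  unknown <- setdiff(haplotypes, names(ref$haplotypes))
  if (length(unknown) > 0) {
    stop("unknown haplotype name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  carried <- unique(unlist(ref$haplotypes[haplotypes]))
  ligand_copies <- c(
    C1k = sum(diplotype$c_groups == "C1k"),
    C2k = sum(diplotype$c_groups == "C2k"),
    Bw4 = diplotype$bw4_count
  )
  hits <- ref$rules[ref$rules$kir_gene %in% carried &
                      ligand_copies[ref$rules$ligand_group] >= 1, ,
                    drop = FALSE]
  if (nrow(hits) > 0) {
    carrier <- vapply(seq_len(nrow(hits)), function(i) {
      listed <- strsplit(hits$haplotypes[i], ",", fixed = TRUE)[[1]]
      own <- haplotypes[vapply(haplotypes, function(h) {
        hits$kir_gene[i] %in% ref$haplotypes[[h]]
      }, logical(1))]
      pref <- intersect(own, listed)
      if (length(pref) > 0) pref[1] else own[1]
    }, character(1))
    weight <- if (dose_weighted) ligand_copies[hits$ligand_group] else 1L
    engagements <- data.frame(
      ligand_group = hits$ligand_group, kir_gene = hits$kir_gene,
      mode = hits$mode, haplotype = carrier, weight = as.integer(weight),
      stringsAsFactors = FALSE
    )
  } else {
    engagements <- data.frame(ligand_group = character(0),
                              kir_gene = character(0), mode = character(0),
                              haplotype = character(0), weight = integer(0),
                              stringsAsFactors = FALSE)
  }
  structure(list(
    subject_id = diplotype$subject_id,
    engagements = engagements,
    n_activating = sum(engagements$weight[engagements$mode == "activates"]),
    n_inhibitory = sum(engagements$weight[engagements$mode == "inhibits"]),
    potential_inhibitory = potential_inhibitory(diplotype)
  ), class = "interaction_profile")
}

#' Cohort means of activating and inhibitory KIR gene copies
#'
#' Sums each subject's diploid copies over the activating genes (2DS2,
#' 2DS3/5c, 3DS1, 2DS3/5t, 2DS1, 2DS4) and over the inhibitory genes
#' (3DL3, 2DL2, 2DL5c, 2DL1, 2DL4, 3DL1, 2DL5t, 3DL2, 2DL3); pseudogenes
#' are excluded. Untyped genes contribute nothing.
#'
#' @param cohort List of `gcn_profile` objects or wide GCN data.frame.
#' @param ref A `kir_reference` bundle.
#' @param per `"subject"` (diploid mean) or `"haplotype"` (mean per
#'   chromosome, i.e. diploid mean / 2).
#' @return Named numeric vector `c(activating = , inhibitory = )`.
#' @export
pooled_gene_counts <- function(cohort, ref = load_reference(),
                               per = c("subject", "haplotype")) {
  per <- match.arg(per)
  mat <- .cohort_gcn_matrix(cohort)
  if (nrow(mat) == 0) stop("cohort is empty", call. = FALSE)
  cls <- ref$genes$class[match(colnames(mat), ref$genes$gene)]
  sums <- function(k) {
    cols <- which(cls == k)
    if (length(cols) == 0) return(rep(0, nrow(mat)))
    rowSums(mat[, cols, drop = FALSE], na.rm = TRUE)
  }
  denom <- if (per == "haplotype") 2 else 1
  c(activating = mean(sums("activating")) / denom,
    inhibitory = mean(sums("inhibitory")) / denom)
}
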