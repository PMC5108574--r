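#' Normalise an HLA allele label
#'
#' Accepts serological ("Cw7", "B44"), family ("C*07") and molecular
#' ("C*07:02") dialects and reduces them to the resolution the ligand
#' classification operates at: two-digit family for HLA-C ("C*07"),
#' serological numeric label for HLA-A/B ("B44", "A24").
#'
#' @param allele Allele label.
#' @param locus `"A"`, `"B"` or `"C"`.
#' @return Normalised label.
#' @export
normalize_hla <- function(allele, locus) {
  allele <- toupper(trimws(as.character(allele)))
  m <- regmatches(allele, regexec("^([ABC])[W*]?\\*?0*([0-9]+)", allele))[[1]]
  if (length(m) == 0 || m[2] != locus || !nzchar(m[3])) {
    stop("cannot parse HLA-", locus, " allele label '", allele, "'",
         call. = FALSE)
  }
  num <- as.integer(m[3])
  if (locus == "C") sprintf("C*%02d", num) else paste0(locus, num)
}

#' Classify an HLA-C allele into its KIR ligand group
#'
#' HLA-C peptide-binding alleles split exhaustively by residue 80: the
#' asparagine-80 families form group C1 (ligand of 2DL2/2DL3/2DS2), the
#' lysine-80 families group C2 (ligand of 2DL1/2DS1). Classification is at
#' two-digit family resolution; higher-resolution labels are truncated.
#'
#' @param allele HLA-C allele label in any accepted dialect.
#' @param ref A `kir_reference` bundle.
#' @return `"C1k"` or `"C2k"`.
#' @export
classify_c_allele <- function(allele, ref = load_reference()) {
  fam <- normalize_hla(allele, "C")
  if (fam %in% ref$ligands$c1k_families) return("C1k")
  if (fam %in% ref$ligands$c2k_families) return("C2k")
  stop("HLA-C allele '", allele, "' (family ", fam,
       ") is in neither the C1 nor the C2 ligand list", call. = FALSE)
}

#' Classify an HLA-B allele as Bw4 or Bw6
#'
#' Every HLA-B allele carries one of the mutually exclusive serological
#' epitopes Bw4 (a KIR ligand, engaging 3DL1/3DS1) or Bw6 (binds no KIR).
#'
#' @param allele HLA-B serological or molecular label.
#' @param ref A `kir_reference` bundle.
#' @return `"Bw4"` or `"Bw6"`.
#' @export
classify_b_allele <- function(allele, ref = load_reference()) {
  lab <- normalize_hla(allele, "B")
  if (lab %in% ref$ligands$bw4_b_alleles) "Bw4" else "Bw6"
}

#' Build a subject's KIR-ligand diplotype
#'
#' Classifies the two HLA-C alleles into C1/C2 groups and counts Bw4
#' epitopes over the HLA-B alleles (optionally also A23/A24/A32 when
#' `bw4_on_a = TRUE`; the default follows the B-locus-only convention).
#'
#' @param subject_id Subject identifier.
#' @param c_alleles Character vector of the two HLA-C alleles.
#' @param b_alleles Character vector of the two HLA-B alleles (optional).
#' @param a_alleles Character vector of the two HLA-A alleles (optional).
#' @param ref A `kir_reference` bundle.
#' @param bw4_on_a Count Bw4 on HLA-A as well?
#' @param source `"inherited"` or `"noninherited"`.
#' @return A list of class `ligand_diplotype`: `subject_id`, `c_groups`
#'   (sorted pair), `label` (e.g. `"C1k/C2k"`), `bw4_count`, `source`.
#' @export
diplotype_of <- function(subject_id, c_alleles, b_alleles = NULL,
                         a_alleles = NULL, ref = load_reference(),
                         bw4_on_a = FALSE, source = "inherited") {
  if (length(c_alleles) != 2) {
    stop("subject ", subject_id, ": exactly two HLA-C alleles required",
         call. = FALSE)
  }
  groups <- sort(vapply(c_alleles, classify_c_allele, character(1),
                        ref = ref))
  bw4 <- 0L
  if (!is.null(b_alleles)) {
    bw4 <- bw4 + sum(vapply(b_alleles, classify_b_allele, character(1),
                            ref = ref) == "Bw4")
  }
  if (bw4_on_a && !is.null(a_alleles)) {
    labs <- vapply(a_alleles, normalize_hla, character(1), locus = "A")
    bw4 <- bw4 + sum(labs %in% ref$ligands$bw4_a_alleles)
  }
  structure(list(subject_id = subject_id, c_groups = unname(groups),
                 label = paste(groups, collapse = "/"),
                 bw4_count = as.integer(bw4), source = source),
            class = "ligand_diplotype")
}

#' Non-transmitted parental alleles at one locus
#'
#' Enumerates the transmission assignments (which allele each parent gave
#' the child) consistent with the trio's genotypes. If none exists the trio
#' is Mendelian-inconsistent; if more than one distinct assignment exists
#' the transmission is ambiguous (typically through shared homozygosity)
#' and the trio is uninformative at this locus.
#'
#' @param father,mother,child Character vectors of the two allele labels of
#'   each trio member (already normalised or raw; compared as given).
#' @return A list: `status` (`"ok"`/`"ambiguous"`), `nontransmitted`
#'   (length-2 vector, father's then mother's untransmitted allele, `NA`
#'   when ambiguous), `transmitted` (same layout).
#' @export
noninherited_alleles <- function(father, mother, child) {
  stopifnot(length(father) == 2, length(mother) == 2, length(child) == 2)
  father <- unname(father)
  mother <- unname(mother)
  child <- unname(child)
  assignments <- list()
  for (fi in 1:2) {
    for (mi in 1:2) {
      if (identical(sort(c(father[fi], mother[mi])), sort(child))) {
        assignments <- c(assignments, list(c(f = father[fi], m = mother[mi])))
      }
    }
  }
  if (length(assignments) == 0) {
    stop("Mendelian inconsistency: father (", paste(father, collapse = ","),
         "), mother (", paste(mother, collapse = ","), "), child (",
         paste(child, collapse = ","), ")", call. = FALSE)
  }
  distinct <- unique(assignments)
  if (length(distinct) > 1) {
    return(list(status = "ambiguous",
                nontransmitted = c(NA_character_, NA_character_),
                transmitted = c(NA_character_, NA_character_)))
  }
  tr <- distinct[[1]]
  nt_f <- father[match(tr["f"], father)[1] %% 2 + 1]
  nt_m <- mother[match(tr["m"], mother)[1] %% 2 + 1]
  # match() on a homozygote returns index 1; the complement rule above maps
  # index 1 -> 2 and 2 -> 1, so the untransmitted copy is always the other
  # slot.
  list(status = "ok", nontransmitted = unname(c(nt_f, nt_m)),
       transmitted = unname(tr))
}

#' Non-inherited (AFBAC) ligand diplotype of a trio
#'
#' The two parental HLA-C alleles NOT transmitted to the child form an
#' internal control "pseudo-subject": non-inherited alleles are drawn from
#' the same families but unexposed to selection on the phenotype.
#'
#' @param father_c,mother_c,child_c The two HLA-C alleles of each member.
#' @param ref A `kir_reference` bundle.
#' @param subject_id Identifier for the control pseudo-subject.
#' @return A `ligand_diplotype` with `source = "noninherited"`, or a list
#'   with `status = "ambiguous"` when transmission cannot be resolved.
#' @export
noninherited_diplotype <- function(father_c, mother_c, child_c,
                                   ref = load_reference(),
                                   subject_id = "noninherited") {
  fam <- function(x) vapply(x, normalize_hla, character(1), locus = "C")
  res <- noninherited_alleles(fam(father_c), fam(mother_c), fam(child_c))
  if (res$status == "ambiguous") {
    return(list(status = "ambiguous", subject_id = subject_id))
  }
  diplotype_of(subject_id, res$nontransmitted, ref = ref,
               source = "noninherited")
}
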