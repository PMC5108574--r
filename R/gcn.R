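#' Per-subject KIR gene copy-number profile
#'
#' Validates a copy-number mapping: integer copies in 0..3 (gene-content
#' typing resolves at most one duplication per locus), and framework genes
#' (3DP1, 2DL4, and when typed 3DL3, 3DL2) present in at least one copy.
#' Genes absent from `copies` are treated as untyped, not as zero.
#'
#' @param subject_id Subject identifier.
#' @param copies Named integer vector, gene symbol -> diploid copy count.
#' @return A list of class `gcn_profile`.
#' @export
gcn_profile <- function(subject_id, copies) {
  if (is.null(names(copies)) || any(!nzchar(names(copies)))) {
    stop("copies must be a named vector of gene copy counts", call. = FALSE)
  }
  unknown <- setdiff(names(copies), kir_genes()$gene)
  if (length(unknown) > 0) {
    stop("unknown KIR gene(s) for subject ", subject_id, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(copies)) || any(copies != round(copies)) ||
      any(copies < 0) || any(copies > 3)) {
    stop("copy counts for subject ", subject_id,
         " must be integers in [0, 3]", call. = FALSE)
  }
  framework <- intersect(c("3DP1", "2DL4", "3DL3", "3DL2"), names(copies))
  low <- framework[copies[framework] < 1]
  if (length(low) > 0) {
    stop("framework gene(s) ", paste(low, collapse = ", "),
         " have zero copies for subject ", subject_id, call. = FALSE)
  }
  # shared typing loci move together; unequal counts are suspicious but
  # tolerated
  for (pair in list(c("2DL5c", "2DS35c"), c("2DL5t", "2DS35t"))) {
    if (all(pair %in% names(copies)) && copies[pair[1]] != copies[pair[2]]) {
      warning("subject ", subject_id, ": shared loci ", pair[1], "/",
              pair[2], " have unequal copy counts", call. = FALSE)
    }
  }
  structure(list(subject_id = subject_id,
                 copies = stats::setNames(as.integer(copies), names(copies))),
            class = "gcn_profile")
}

#' Presence/absence genotype from a copy-number profile
#'
#' Genotyping only resolves whether a gene is absent or present; this is
#' the projection GCN -> genotype (present iff copies >= 1).
#'
#' @param profile A `gcn_profile`.
#' @return Named character vector with values `"present"`/`"absent"`.
#' @export
presence_from_gcn <- function(profile) {
  stopifnot(inherits(profile, "gcn_profile"))
  ifelse(profile$copies >= 1, "present", "absent")
}

# round half-up to `digits` decimals (matches how the printed ratios round)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Cohort GCN / genotype summary
#'
#' For each typed gene, tallies the presence/absence genotype, the copy
#' number distribution, the total diploid copies, and the ratio
#' total copies / subjects carrying the gene. A ratio near 1 means carriers
#' hold a single copy; near 2 means the gene sits on both chromosomes
#' (framework genes); between 1 and 2 means a mix.
#'
#' @param cohort A list of `gcn_profile` objects, or a data.frame with a
#'   `subject_id` column and one integer column per gene.
#' @return A data.frame with columns `gene`, `present`, `absent`,
#'   `gcn0`..`gcn3`, `total_copies`, `ratio` (2 d.p., half-up; `NA` when no
#'   carrier).
#' @export
gcn_ratio_table <- function(cohort) {
  mat <- .cohort_gcn_matrix(cohort)
  if (nrow(mat) == 0) stop("cohort is empty", call. = FALSE)
  out <- lapply(colnames(mat), function(g) {
    x <- mat[, g]
    x <- x[!is.na(x)]
    present <- sum(x >= 1)
    total <- sum(x)
    data.frame(
      gene = g, present = present, absent = sum(x == 0),
      gcn0 = sum(x == 0), gcn1 = sum(x == 1), gcn2 = sum(x == 2),
      gcn3 = sum(x == 3), total_copies = total,
      ratio = if (present > 0) round_half_up(total / present, 2) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# cohort (list of profiles or wide data.frame) -> subjects x genes matrix
.cohort_gcn_matrix <- function(cohort) {
  if (is.data.frame(cohort)) {
    genes <- setdiff(colnames(cohort), "subject_id")
    mat <- as.matrix(cohort[, genes, drop = FALSE])
    storage.mode(mat) <- "integer"
    rownames(mat) <- if ("subject_id" %in% colnames(cohort)) {
      as.character(cohort$subject_id)
    } else NULL
    return(mat)
  }
  stopifnot(is.list(cohort), length(cohort) > 0)
  genes <- unique(unlist(lapply(cohort, function(p) names(p$copies))))
  mat <- matrix(NA_integer_, nrow = length(cohort), ncol = length(genes),
                dimnames = list(vapply(cohort, function(p) p$subject_id,
                                       character(1)), genes))
  for (i in seq_along(cohort)) {
    mat[i, names(cohort[[i]]$copies)] <- cohort[[i]]$copies
  }
  mat
}

# all unordered pairs (with replacement) of haplotype names
.unordered_pairs <- function(haps) {
  idx <- which(upper.tri(diag(length(haps)), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(i) haps[c(idx[i, 1], idx[i, 2])])
}

#' Deconvolve one region's copy numbers into a haplotype pair
#'
#' Exhaustively enumerates all unordered pairs (with replacement) of the
#' reference motifs for the region and retains every pair whose summed
#' gene-content vector matches the observed copy numbers exactly. If a gene
#' shows 3 copies, matching is retried after peeling one copy off each such
#' gene (single-gene duplication, carried by roughly 4.5% of Caucasian
#' haplotypes for 3DP1/2DL4) and the result is flagged `duplication`.
#'
#' @param profile A `gcn_profile`; must type every gene of the region.
#' @param region `"centromeric"` or `"telomeric"`.
#' @param ref A `kir_reference` bundle.
#' @return A list of class `haplotype_pair`: `subject_id`, `region`,
#'   `status` (`unique`/`ambiguous`/`unresolved`), `pairs` (list of
#'   2-vectors of motif names), `flags`.
#' @export
deconvolve_region <- function(profile, region, ref = load_reference()) {
  stopifnot(inherits(profile, "gcn_profile"),
            region %in% c("centromeric", "telomeric"))
  region_genes <- ref$genes$gene[ref$genes$region == region]
  missing <- setdiff(region_genes, names(profile$copies))
  if (length(missing) > 0) {
    stop("subject ", profile$subject_id, " lacks copy numbers for ",
         region, " gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  observed <- profile$copies[region_genes]
  haps <- region_haplotypes(ref, region)
  contents <- vapply(haps, haplotype_content, integer(length(region_genes)),
                     ref = ref, region = region)
  candidates <- .unordered_pairs(haps)
  match_pairs <- function(target) {
    Filter(function(pr) {
      all(contents[, pr[1]] + contents[, pr[2]] == target)
    }, candidates)
  }
  pairs <- match_pairs(observed)
  flags <- character(0)
  if (length(pairs) == 0 && any(observed == 3)) {
    for (g in names(observed)[observed == 3]) {
      reduced <- observed
      reduced[g] <- reduced[g] - 1L
      hit <- match_pairs(reduced)
      if (length(hit) > 0) {
        pairs <- c(pairs, hit)
        flags <- union(flags, "duplication")
      }
    }
    # multiple simultaneous duplications (e.g. two loci at 3 copies)
    if (length(pairs) == 0 && sum(observed == 3) > 1) {
      reduced <- observed
      reduced[observed == 3] <- 2L
      hit <- match_pairs(reduced)
      if (length(hit) > 0) {
        pairs <- hit
        flags <- union(flags, "duplication")
      }
    }
  }
  pairs <- unique(pairs)
  status <- if (length(pairs) == 0) "unresolved"
            else if (length(pairs) == 1) "unique" else "ambiguous"
  structure(list(subject_id = profile$subject_id, region = region,
                 status = status, pairs = pairs, flags = flags),
            class = "haplotype_pair")
}

#' Assemble complete (centromeric + telomeric) haplotypes
#'
#' Joins a subject's resolved centromeric and telomeric motif pairs into
#' two complete chromosome-scale haplotypes. If at least one region is
#' homozygous the pairing is forced. When both regions are heterozygous the
#' two possible phasings are distinguished only if `family_phase` (the
#' parents' candidate complete haplotypes) makes exactly one phasing
#' Mendelian-consistent; otherwise the subject is left undetermined and
#' contributes no complete haplotypes downstream.
#'
#' @param cent,tel `haplotype_pair` objects with status `"unique"`.
#' @param family_phase Optional list with elements `father` and `mother`,
#'   each a character vector of candidate complete haplotypes
#'   (`"cent/tel"` strings) obtainable from that parent.
#' @return A list of class `complete_call`: `subject_id`, `calls`
#'   (character vector of `"cent/tel"` names, length 2 when determined,
#'   else 0), `determined`.
#' @export
assemble_complete <- function(cent, tel, family_phase = NULL) {
  stopifnot(inherits(cent, "haplotype_pair"), inherits(tel, "haplotype_pair"))
  if (cent$status != "unique" || tel$status != "unique") {
    stop("assemble_complete requires unique region pairs; resolve ",
         "ambiguous/unresolved regions first (subject ",
         cent$subject_id, ")", call. = FALSE)
  }
  cp <- cent$pairs[[1]]
  tp <- tel$pairs[[1]]
  phasings <- unique(list(
    sort(paste(c(cp[1], cp[2]), c(tp[1], tp[2]), sep = "/")),
    sort(paste(c(cp[1], cp[2]), c(tp[2], tp[1]), sep = "/"))
  ))
  if (length(phasings) == 1) {
    return(structure(list(subject_id = cent$subject_id,
                          calls = phasings[[1]], determined = TRUE),
                     class = "complete_call"))
  }
  if (!is.null(family_phase)) {
    consistent <- vapply(phasings, function(ph) {
      (ph[1] %in% family_phase$father && ph[2] %in% family_phase$mother) ||
        (ph[2] %in% family_phase$father && ph[1] %in% family_phase$mother)
    }, logical(1))
    if (sum(consistent) == 1) {
      return(structure(list(subject_id = cent$subject_id,
                            calls = phasings[[which(consistent)]],
                            determined = TRUE),
                       class = "complete_call"))
    }
  }
  structure(list(subject_id = cent$subject_id, calls = character(0),
                 determined = FALSE),
            class = "complete_call")
}

#' Candidate complete haplotypes compatible with a subject's region calls
#'
#' Every `"cent/tel"` combination drawn from the subject's possible
#' centromeric and telomeric motifs, across all retained pairs. Used as the
#' `family_phase` input when phasing a child against its parents: it is a
#' superset of the parent's true two haplotypes, so a phasing rejected
#' against it is truly inconsistent.
#'
#' @param cent,tel `haplotype_pair` objects (any status).
#' @return Character vector of `"cent/tel"` names (possibly empty).
#' @export
candidate_completes <- function(cent, tel) {
  cs <- unique(unlist(cent$pairs))
  ts <- unique(unlist(tel$pairs))
  if (length(cs) == 0 || length(ts) == 0) return(character(0))
  as.vector(outer(cs, ts, paste, sep = "/"))
}
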