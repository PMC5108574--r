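#' KIR gene catalogue
#'
#' The 17 loci of the KIR complex as typed at gene-content resolution:
#' 15 genes plus the two pseudogenes 2DP1 and 3DP1. 2DL5 and the 2DS3/2DS5
#' pair are typed as shared loci with distinct centromeric (`2DL5c`,
#' `2DS35c`) and telomeric (`2DL5t`, `2DS35t`) entries. Each locus belongs
#' to one region (centromeric or telomeric) and one functional class:
#' activating (short-tailed, ...S...), inhibitory (long-tailed, ...L...)
#' or pseudogene.
#'
#' @return A data.frame with columns `gene`, `region`, `class`.
#' @export
kir_genes <- function() {
  data.frame(
    gene = c("3DL3", "2DS2", "2DL2", "2DL3", "2DL5c", "2DS35c", "2DP1",
             "2DL1", "3DP1",
             "2DL4", "3DL1", "3DS1", "2DL5t", "2DS35t", "2DS1", "2DS4",
             "3DL2"),
    region = c(rep("centromeric", 9), rep("telomeric", 8)),
    class = c("inhibitory", "activating", "inhibitory", "inhibitory",
              "inhibitory", "activating", "pseudogene",
              "inhibitory", "pseudogene",
              "inhibitory", "inhibitory", "activating", "inhibitory",
              "activating", "activating", "activating",
              "inhibitory"),
    stringsAsFactors = FALSE
  )
}

# Gene-content definitions of the six common centromeric/telomeric motifs.
# Framework genes: 3DL3 on every centromeric motif; 2DL4 and 3DL2 on every
# telomeric motif; 3DP1 near-universal centromerically.
.default_haplotypes <- function() {
  list(
    cA01 = c("3DL3", "2DL3", "2DP1", "2DL1", "3DP1"),
    cB01 = c("3DL3", "2DS2", "2DL2", "2DL5c", "2DS35c", "2DP1", "2DL1",
             "3DP1"),
    cB02 = c("3DL3", "2DS2", "2DL2", "3DP1"),
    cB03 = c("3DL3", "2DS2", "2DL3", "2DP1", "2DL1", "3DP1"),
    tA01 = c("2DL4", "3DL1", "2DS4", "3DL2"),
    tB01 = c("2DL4", "3DS1", "2DL5t", "2DS35t", "2DS1", "3DL2")
  )
}

# HLA ligand-group allele lists. HLA-C splits exhaustively into the C1
# (asparagine 80) and C2 (lysine 80) KIR-binding groups at two-digit family
# resolution; the listed HLA-B serological alleles carry the Bw4 epitope
# (residues 77-83), all others carry Bw6 which binds no KIR. A23/A24/A32
# also carry Bw4 and can optionally be counted.
.default_ligands <- function() {
  list(
    c1k_families = c("C*01", "C*03", "C*07", "C*08", "C*12", "C*14",
                     "C*16"),
    c2k_families = c("C*02", "C*04", "C*05", "C*06", "C*15", "C*17",
                     "C*18"),
    bw4_b_alleles = c("B5", "B13", "B17", "B27", "B37", "B38", "B44",
                      "B47", "B49", "B51", "B52", "B53", "B57", "B58",
                      "B59", "B63", "B77"),
    bw4_a_alleles = c("A23", "A24", "A32")
  )
}

# Ligand-group x KIR-gene engagement rules. `haplotypes` records the
# motifs on which the rule's gene rides; rule firing tests actual gene
# carriage, so motifs sharing the gene (e.g. cB03 carrying 2DL3) are
# covered automatically. Bw4 engages only telomeric receptors, C1/C2 only
# centromeric ones except for the 2DS1 rule.
.default_rules <- function() {
  data.frame(
    ligand_group = c("C1k", "C2k", "C1k", "C1k", "Bw4", "Bw4", "C2k"),
    kir_gene = c("2DL3", "2DL1", "2DL2", "2DS2", "3DL1", "3DS1", "2DS1"),
    mode = c("inhibits", "inhibits", "inhibits", "activates", "inhibits",
             "activates", "activates"),
    haplotypes = c("cA01", "cA01,cB01", "cB01,cB02", "cB01,cB02", "tA01",
                   "tB01", "tB01"),
    stringsAsFactors = FALSE
  )
}

#' Load the immunogenetic reference bundle
#'
#' Assembles the immutable reference data the pipeline runs against: the
#' KIR gene catalogue, the gene-content definitions of the centromeric
#' (cA01, cB01, cB02, cB03) and telomeric (tA01, tB01) haplotype motifs,
#' the HLA ligand-group allele lists, and the ligand/receptor engagement
#' rule matrix.
#'
#' A YAML configuration file may extend the bundle: the `haplotypes`
#' section adds named motif definitions (each a list of known gene
#' symbols), `ligand_lists` adds alleles to a ligand group, and
#' `interaction_rules` adds rules. Gene classes and existing definitions
#' cannot be mutated.
#'
#' @param config_path Optional path to a YAML configuration file.
#' @return An object of class `kir_reference`: a list with elements
#'   `genes`, `haplotypes`, `ligands`, `rules`.
#' @export
load_reference <- function(config_path = NULL) {
  ref <- structure(
    list(
      genes = kir_genes(),
      haplotypes = .default_haplotypes(),
      ligands = .default_ligands(),
      rules = .default_rules()
    ),
    class = "kir_reference"
  )
  if (!is.null(config_path)) {
    cfg <- tryCatch(
      yaml::read_yaml(config_path),
      error = function(e) stop("malformed reference config '", config_path,
                               "': ", conditionMessage(e), call. = FALSE)
    )
    ref <- .apply_reference_config(ref, cfg)
  }
  .validate_reference(ref)
  ref
}

.apply_reference_config <- function(ref, cfg) {
  allowed <- c("haplotypes", "ligand_lists", "interaction_rules")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0) {
    stop("configuration error: unknown or immutable section(s): ",
         paste(bad, collapse = ", "),
         " (gene classes and the gene catalogue cannot be modified)",
         call. = FALSE)
  }
  known_genes <- ref$genes$gene
  for (hname in names(cfg$haplotypes)) {
    genes <- unlist(cfg$haplotypes[[hname]])
    unknown <- setdiff(genes, known_genes)
    if (length(unknown) > 0) {
      stop("configuration error: haplotype '", hname,
           "' references unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    regions <- unique(ref$genes$region[match(genes, ref$genes$gene)])
    if (length(regions) != 1) {
      stop("configuration error: haplotype '", hname,
           "' mixes centromeric and telomeric genes", call. = FALSE)
    }
    if (hname %in% names(ref$haplotypes)) {
      stop("configuration error: haplotype '", hname,
           "' already defined; existing definitions are immutable",
           call. = FALSE)
    }
    ref$haplotypes[[hname]] <- genes
  }
  for (lname in names(cfg$ligand_lists)) {
    if (!lname %in% names(ref$ligands)) {
      stop("configuration error: unknown ligand list '", lname, "'",
           call. = FALSE)
    }
    ref$ligands[[lname]] <- union(ref$ligands[[lname]],
                                  unlist(cfg$ligand_lists[[lname]]))
  }
  for (rule in cfg$interaction_rules) {
    if (!all(c("ligand_group", "kir_gene", "mode") %in% names(rule))) {
      stop("configuration error: interaction rule missing one of ",
           "ligand_group/kir_gene/mode", call. = FALSE)
    }
    if (!rule$kir_gene %in% known_genes) {
      stop("configuration error: rule references unknown gene '",
           rule$kir_gene, "'", call. = FALSE)
    }
    ref$rules <- rbind(ref$rules, data.frame(
      ligand_group = rule$ligand_group, kir_gene = rule$kir_gene,
      mode = rule$mode,
      haplotypes = paste(unlist(rule$haplotypes), collapse = ","),
      stringsAsFactors = FALSE
    ))
  }
  ref
}

.validate_reference <- function(ref) {
  # region purity and framework-gene invariants
  for (hname in names(ref$haplotypes)) {
    genes <- ref$haplotypes[[hname]]
    regions <- unique(ref$genes$region[match(genes, ref$genes$gene)])
    stopifnot(length(regions) == 1)
    if (regions == "centromeric" && !"3DL3" %in% genes) {
      stop("reference error: centromeric haplotype '", hname,
           "' lacks framework gene 3DL3", call. = FALSE)
    }
    if (regions == "telomeric" && !all(c("2DL4", "3DL2") %in% genes)) {
      stop("reference error: telomeric haplotype '", hname,
           "' lacks framework gene 2DL4 or 3DL2", call. = FALSE)
    }
  }
  # rule closure: every rule gene is carried by at least one listed motif
  for (i in seq_len(nrow(ref$rules))) {
    haps <- strsplit(ref$rules$haplotypes[i], ",", fixed = TRUE)[[1]]
    carried <- vapply(haps, function(h) {
      ref$rules$kir_gene[i] %in% ref$haplotypes[[h]]
    }, logical(1))
    if (!all(carried)) {
      stop("reference error: rule ", ref$rules$ligand_group[i], ":",
           ref$rules$kir_gene[i], " lists a haplotype not carrying the gene",
           call. = FALSE)
    }
  }
  # ligand families are disjoint
  overlap <- intersect(ref$ligands$c1k_families, ref$ligands$c2k_families)
  if (length(overlap) > 0) {
    stop("reference error: C1/C2 family lists overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  invisible(ref)
}

#' Gene-content vector of a haplotype motif
#'
#' @param ref A `kir_reference` bundle.
#' @param name Haplotype motif name (e.g. `"cB01"`).
#' @param region Optionally restrict/order the vector over one region's
#'   genes; defaults to the motif's own region.
#' @return Named integer vector of copy counts (0/1) over the region's
#'   genes.
#' @export
haplotype_content <- function(ref, name, region = NULL) {
  if (!name %in% names(ref$haplotypes)) {
    stop("unknown haplotype name '", name, "'", call. = FALSE)
  }
  genes <- ref$haplotypes[[name]]
  if (is.null(region)) {
    region <- ref$genes$region[match(genes[1], ref$genes$gene)]
  }
  region_genes <- ref$genes$gene[ref$genes$region == region]
  stats::setNames(as.integer(region_genes %in% genes), region_genes)
}

#' Haplotype motif names of one region
#'
#' @param ref A `kir_reference` bundle.
#' @param region `"centromeric"` or `"telomeric"`.
#' @return Character vector of motif names.
#' @export
region_haplotypes <- function(ref, region) {
  names(ref$haplotypes)[vapply(ref$haplotypes, function(genes) {
    ref$genes$region[match(genes[1], ref$genes$gene)] == region
  }, logical(1))]
}

#' @export
print.kir_reference <- function(x, ...) {
  cat("KIR reference bundle\n")
  cat("  genes:      ", nrow(x$genes), "\n")
  cat("  haplotypes: ", paste(names(x$haplotypes), collapse = ", "), "\n")
  cat("  rules:      ", nrow(x$rules), "\n")
  invisible(x)
}
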