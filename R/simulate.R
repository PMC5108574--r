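#' Default control-population complete-haplotype frequencies
#'
#' Proportions of the six common complete (centromeric/telomeric) KIR
#' gene-content haplotypes in a large Caucasian reference panel of 9,024
#' haplotypes, normalised over the six named combinations.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_haplotype_freqs <- function() {
  counts <- c("cA01/tA01" = 5133, "cA01/tB01" = 1114, "cB01/tA01" = 697,
              "cB01/tB01" = 461, "cB02/tA01" = 1112, "cB02/tB01" = 480)
  counts / sum(counts)
}

#' Default HLA-C family frequencies
#'
#' Family-level allele frequencies chosen so the aggregate C1-group
#' frequency is 0.59 (the value implied by the non-inherited parental
#' alleles of the AGRE trios), with the mass distributed over families at
#' roughly their common European proportions.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_c_family_freqs <- function() {
  c("C*07" = 0.25, "C*03" = 0.12, "C*12" = 0.08, "C*01" = 0.05,
    "C*08" = 0.05, "C*14" = 0.02, "C*16" = 0.02,
    "C*04" = 0.18, "C*05" = 0.08, "C*06" = 0.08, "C*02" = 0.04,
    "C*15" = 0.02, "C*17" = 0.005, "C*18" = 0.005)
}

#' Default HLA-B serological allele frequencies
#'
#' A compact serological panel with an aggregate Bw4 epitope frequency of
#' 0.35, typical of European populations.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_b_allele_freqs <- function() {
  c("B44" = 0.12, "B51" = 0.06, "B57" = 0.04, "B27" = 0.04, "B13" = 0.03,
    "B38" = 0.02, "B17" = 0.02, "B37" = 0.01, "B49" = 0.01,
    "B7" = 0.12, "B8" = 0.10, "B35" = 0.10, "B62" = 0.10, "B40" = 0.08,
    "B60" = 0.05, "B14" = 0.05, "B18" = 0.05)
}

#' Simulation configuration for synthetic trio cohorts
#'
#' @param n_families Number of proband trios (default 89, the AGRE cohort
#'   size).
#' @param kir_complete_haplotype_freqs Named frequencies of complete
#'   `"cent/tel"` haplotypes (must sum to 1).
#' @param c_family_freqs Named HLA-C family frequencies (sum to 1).
#' @param b_allele_freqs Named HLA-B serological allele frequencies (sum
#'   to 1).
#' @param transmission_tau Probability that a parent heterozygous for the
#'   risk target transmits it to the (affected) child; 0.5 is the null.
#' @param risk_target A complete haplotype name (e.g. `"cB01/tA01"`) or a
#'   ligand group (`"C1k"`/`"C2k"`).
#' @param case_enrichment_or Per-risk-copy odds ratio of affection; 1
#'   disables ascertainment enrichment.
#' @param base_prevalence Affection probability with zero risk copies
#'   (logistic baseline; only used when `case_enrichment_or != 1`).
#' @param duplication_rate Per-subject probability of the 3DP1/2DL4
#'   single-gene duplication (default 0.045).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_families = 89,
                              kir_complete_haplotype_freqs =
                                default_haplotype_freqs(),
                              c_family_freqs = default_c_family_freqs(),
                              b_allele_freqs = default_b_allele_freqs(),
                              transmission_tau = 0.5,
                              risk_target = "cB01/tA01",
                              case_enrichment_or = 1,
                              base_prevalence = 0.02,
                              duplication_rate = 0.045,
                              seed = NULL) {
  for (f in list(kir_complete_haplotype_freqs, c_family_freqs,
                 b_allele_freqs)) {
    if (is.null(names(f)) || abs(sum(f) - 1) > 1e-9 || any(f < 0)) {
      stop("frequency vectors must be named, non-negative and sum to 1",
           call. = FALSE)
    }
  }
  stopifnot(n_families >= 1, transmission_tau >= 0, transmission_tau <= 1,
            case_enrichment_or > 0, base_prevalence > 0,
            base_prevalence < 1, duplication_rate >= 0,
            duplication_rate < 1)
  structure(list(
    n_families = as.integer(n_families),
    hap_freqs = kir_complete_haplotype_freqs,
    c_freqs = c_family_freqs,
    b_freqs = b_allele_freqs,
    tau = transmission_tau,
    risk_target = risk_target,
    or = case_enrichment_or,
    base_prevalence = base_prevalence,
    duplication_rate = duplication_rate,
    seed = seed
  ), class = "sim_config")
}

# transmit one allele per row of a two-column matrix; rows heterozygous for
# `risk` transmit it with probability tau, all other rows are fair coin
.transmit <- function(mat, tau = 0.5, risk = NULL,
                      is_risk = function(x) x == risk) {
  n <- nrow(mat)
  p_first <- rep(0.5, n)
  if (!is.null(risk)) {
    r1 <- is_risk(mat[, 1])
    r2 <- is_risk(mat[, 2])
    het <- xor(r1, r2)
    p_first[het & r1] <- tau
    p_first[het & r2] <- 1 - tau
  }
  idx <- ifelse(stats::runif(n) < p_first, 1L, 2L)
  list(allele = mat[cbind(seq_len(n), idx)], index = idx)
}

.draw_pairs <- function(n, freqs) {
  matrix(sample(names(freqs), 2 * n, replace = TRUE, prob = freqs),
         nrow = n, ncol = 2)
}

# one batch of trios as a data.frame (before ascertainment)
.simulate_batch <- function(n, config) {
  risk_hap <- if (config$risk_target %in% names(config$hap_freqs)) {
    config$risk_target
  } else NULL
  risk_cgroup <- if (config$risk_target %in% c("C1k", "C2k")) {
    config$risk_target
  } else NULL
  c1k <- .default_ligands()$c1k_families
  cgroup_of <- function(fam) ifelse(fam %in% c1k, "C1k", "C2k")

  fa_hap <- .draw_pairs(n, config$hap_freqs)
  mo_hap <- .draw_pairs(n, config$hap_freqs)
  fa_c <- .draw_pairs(n, config$c_freqs)
  mo_c <- .draw_pairs(n, config$c_freqs)
  fa_b <- .draw_pairs(n, config$b_freqs)
  mo_b <- .draw_pairs(n, config$b_freqs)

  t_fa_hap <- .transmit(fa_hap, config$tau, risk_hap)
  t_mo_hap <- .transmit(mo_hap, config$tau, risk_hap)
  if (!is.null(risk_cgroup)) {
    is_risk_c <- function(x) cgroup_of(x) == risk_cgroup
    t_fa_c <- .transmit(fa_c, config$tau, risk = "group", is_risk = is_risk_c)
    t_mo_c <- .transmit(mo_c, config$tau, risk = "group", is_risk = is_risk_c)
  } else {
    t_fa_c <- .transmit(fa_c)
    t_mo_c <- .transmit(mo_c)
  }
  t_fa_b <- .transmit(fa_b)
  t_mo_b <- .transmit(mo_b)

  data.frame(
    fa_hap1 = fa_hap[, 1], fa_hap2 = fa_hap[, 2],
    mo_hap1 = mo_hap[, 1], mo_hap2 = mo_hap[, 2],
    ch_hap1 = t_fa_hap$allele, ch_hap2 = t_mo_hap$allele,
    fa_c1 = fa_c[, 1], fa_c2 = fa_c[, 2],
    mo_c1 = mo_c[, 1], mo_c2 = mo_c[, 2],
    ch_c1 = t_fa_c$allele, ch_c2 = t_mo_c$allele,
    fa_b1 = fa_b[, 1], fa_b2 = fa_b[, 2],
    mo_b1 = mo_b[, 1], mo_b2 = mo_b[, 2],
    ch_b1 = t_fa_b$allele, ch_b2 = t_mo_b$allele,
    stringsAsFactors = FALSE
  )
}

# risk copies carried by the child, under either target kind
.child_risk_copies <- function(batch, config) {
  if (config$risk_target %in% c("C1k", "C2k")) {
    c1k <- .default_ligands()$c1k_families
    g1 <- ifelse(batch$ch_c1 %in% c1k, "C1k", "C2k")
    g2 <- ifelse(batch$ch_c2 %in% c1k, "C1k", "C2k")
    (g1 == config$risk_target) + (g2 == config$risk_target)
  } else {
    (batch$ch_hap1 == config$risk_target) +
      (batch$ch_hap2 == config$risk_target)
  }
}

#' Simulate an ascertained cohort of proband trios
#'
#' Parents are drawn from the configured complete-haplotype and HLA allele
#' frequencies; each transmits one haplotype/allele per locus to the child,
#' with Bernoulli(`transmission_tau`) bias toward the risk target in
#' heterozygous parents. When `case_enrichment_or != 1`, affection follows
#' a logistic model with log-odds offset `ln(OR)` per risk copy over a
#' baseline prevalence, and only affected-child trios are retained
#' (proband ascertainment); otherwise every trio is kept and marked
#' affected. KIR and HLA segregate independently (chromosomes 19 and 6).
#'
#' @param config A `sim_config`.
#' @return A data.frame of class `trio_cohort`, one row per family, with
#'   per-member haplotype/allele columns, duplication flags and
#'   `ch_affected`.
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  need <- config$n_families
  kept <- list()
  got <- 0L
  while (got < need) {
    batch_n <- if (config$or == 1) {
      need - got
    } else {
      # oversize the batch against the expected acceptance rate
      p_acc <- config$base_prevalence * max(1, config$or)
      max(1000L, ceiling((need - got) / p_acc * 1.3))
    }
    batch <- .simulate_batch(batch_n, config)
    if (config$or == 1) {
      batch$ch_affected <- 1L
    } else {
      k <- .child_risk_copies(batch, config)
      p_aff <- stats::plogis(stats::qlogis(config$base_prevalence) +
                               log(config$or) * k)
      batch <- batch[stats::runif(batch_n) < p_aff, , drop = FALSE]
      if (nrow(batch) == 0) next
      batch$ch_affected <- 1L
    }
    take <- min(nrow(batch), need - got)
    kept <- c(kept, list(batch[seq_len(take), , drop = FALSE]))
    got <- got + take
  }
  trios <- do.call(rbind, kept)
  rownames(trios) <- NULL
  trios$family_id <- sprintf("F%04d", seq_len(nrow(trios)))
  for (member in c("fa", "mo", "ch")) {
    trios[[paste0(member, "_dup")]] <-
      as.integer(stats::runif(nrow(trios)) < config$duplication_rate)
  }
  class(trios) <- c("trio_cohort", "data.frame")
  trios
}

#' Simulate a control haplotype pool
#'
#' One multinomial draw of `n_haplotypes` complete haplotypes from the
#' configured frequencies, standing in for an external reference panel.
#'
#' @param config A `sim_config`.
#' @param n_haplotypes Pool size (e.g. 9024 chromosomes).
#' @return Named integer vector of haplotype tallies summing to
#'   `n_haplotypes`.
#' @export
simulate_control_pool <- function(config, n_haplotypes) {
  stopifnot(inherits(config, "sim_config"))
  if (n_haplotypes <= 0) stop("n_haplotypes must be positive", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  draw <- stats::rmultinom(1, n_haplotypes, prob = config$hap_freqs)
  stats::setNames(as.integer(draw), names(config$hap_freqs))
}

#' Diploid GCN vector implied by two complete haplotypes
#'
#' @param haps Character vector of two `"cent/tel"` complete haplotype
#'   names.
#' @param ref A `kir_reference` bundle.
#' @param duplication Add one extra copy of 3DP1 and 2DL4 (the common
#'   single-gene duplication)?
#' @return Named integer vector over all 17 loci.
#' @export
gcn_from_haplotypes <- function(haps, ref = load_reference(),
                                duplication = FALSE) {
  stopifnot(length(haps) == 2)
  parts <- strsplit(haps, "/", fixed = TRUE)
  copies <- stats::setNames(integer(nrow(ref$genes)), ref$genes$gene)
  for (p in parts) {
    for (motif in p) {
      genes <- ref$haplotypes[[motif]]
      if (is.null(genes)) stop("unknown motif '", motif, "'", call. = FALSE)
      copies[genes] <- copies[genes] + 1L
    }
  }
  if (duplication) {
    copies[c("3DP1", "2DL4")] <- pmin(copies[c("3DP1", "2DL4")] + 1L, 3L)
  }
  copies
}

#' Tabulate a trio cohort in the pipeline's input schemas
#'
#' Flattens a simulated cohort into the four tables the analysis consumes:
#' `gcn` (wide copy-number table over all members), `hla` (long per-locus
#' allele table), `ped` (family structure) and `truth` (the simulated
#' haplotypes, for validation only).
#'
#' @param trios A `trio_cohort`.
#' @param ref A `kir_reference` bundle.
#' @return Named list of data.frames `gcn`, `hla`, `ped`, `truth`.
#' @export
cohort_tables <- function(trios, ref = load_reference()) {
  members <- c("fa", "mo", "ch")
  # content matrix: one row per complete haplotype name, columns = 17 loci
  complete_names <- unique(unlist(
    trios[paste0(rep(members, each = 2), "_hap", 1:2)]
  ))
  content <- t(vapply(complete_names, function(h) {
    gcn_from_haplotypes(c(h, h), ref) %/% 2L
  }, integer(nrow(ref$genes))))
  sid <- as.vector(vapply(members, function(m) {
    paste0(trios$family_id, "_", m)
  }, character(nrow(trios))))
  h1 <- unlist(lapply(members, function(m) trios[[paste0(m, "_hap1")]]),
               use.names = FALSE)
  h2 <- unlist(lapply(members, function(m) trios[[paste0(m, "_hap2")]]),
               use.names = FALSE)
  dup <- unlist(lapply(members, function(m) trios[[paste0(m, "_dup")]]),
                use.names = FALSE)
  mat <- content[h1, , drop = FALSE] + content[h2, , drop = FALSE]
  mat[dup == 1, c("3DP1", "2DL4")] <-
    pmin(mat[dup == 1, c("3DP1", "2DL4")] + 1L, 3L)
  gcn <- data.frame(subject_id = sid, mat, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  hla <- data.frame(
    subject_id = rep(sid, 2),
    locus = rep(c("C", "B"), each = length(sid)),
    allele1 = c(unlist(lapply(members, function(m) trios[[paste0(m, "_c1")]]),
                       use.names = FALSE),
                unlist(lapply(members, function(m) trios[[paste0(m, "_b1")]]),
                       use.names = FALSE)),
    allele2 = c(unlist(lapply(members, function(m) trios[[paste0(m, "_c2")]]),
                       use.names = FALSE),
                unlist(lapply(members, function(m) trios[[paste0(m, "_b2")]]),
                       use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  ped <- data.frame(
    family_id = trios$family_id,
    subject_id = paste0(trios$family_id, "_ch"),
    father_id = paste0(trios$family_id, "_fa"),
    mother_id = paste0(trios$family_id, "_mo"),
    affected = trios$ch_affected,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(subject_id = sid, hap1 = h1, hap2 = h2,
                      duplication = dup, stringsAsFactors = FALSE)
  list(gcn = gcn, hla = hla, ped = ped, truth = truth)
}

#' Write a synthetic trio cohort in the pipeline's input formats
#'
#' Writes the tables of [cohort_tables()] as TSV files `gcn.tsv`,
#' `hla.tsv`, `ped.tsv` and `truth.tsv`.
#'
#' @param trios A `trio_cohort`.
#' @param dir Output directory (created if needed).
#' @param ref A `kir_reference` bundle.
#' @return Invisibly, the named list of written file paths.
#' @export
write_cohort <- function(trios, dir, ref = load_reference()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- cohort_tables(trios, ref)
  paths <- lapply(stats::setNames(nm = names(tabs)), function(nm) {
    file.path(dir, paste0(nm, ".tsv"))
  })
  for (nm in names(tabs)) {
    utils::write.table(tabs[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
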