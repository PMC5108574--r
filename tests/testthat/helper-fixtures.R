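# shared fixtures: one reference bundle, and builders for profiles whose
# copy numbers are the exact sum of two named haplotypes
ref <- load_reference()

profile_from_pair <- function(cent_pair, tel_pair, subject_id = "S1",
                              duplication = FALSE) {
  copies <- gcn_from_haplotypes(paste(cent_pair, tel_pair, sep = "/"),
                                ref, duplication = duplication)
  gcn_profile(subject_id, copies)
}

cent_pairs_all <- function() {
  haps <- region_haplotypes(ref, "centromeric")
  idx <- which(upper.tri(diag(length(haps)), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(i) haps[c(idx[i, 1], idx[i, 2])])
}

tel_pairs_all <- function() {
  haps <- region_haplotypes(ref, "telomeric")
  idx <- which(upper.tri(diag(length(haps)), diag = TRUE), arr.ind = TRUE)
  lapply(seq_len(nrow(idx)), function(i) haps[c(idx[i, 1], idx[i, 2])])
}
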