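# Shared fixture builders.

two_genome_res <- function(prots_a, prots_b, rm_type = "II", role = "RE") {
  mk <- function(g, prots) {
    do.call(rbind, lapply(seq_along(prots), function(i)
      gene_records(g, paste0(g, "_chr"), names(prots)[i],
                   1000L + i * 5000L, 1000L + i * 5000L + 300L,
                   role = role, rm_type = rm_type,
                   system_id = names(prots)[i], protein_seq = prots[[i]])))
  }
  rbind(mk("gA", prots_a), mk("gB", prots_b))
}
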