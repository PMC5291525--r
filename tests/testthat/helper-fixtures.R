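# Shared fixture: a two-record FASTA with one positive-regime and one
# negative-regime synthetic genome.
make_synth_fasta <- function(dir, seed = 101, N = 20000L) {
  sp_pos <- skew_spec(N = N, ori = 0L, seed = seed)
  sp_neg <- skew_spec(N = N, ori = 0L,
                      leading_probs = regime_probs("keto"), seed = seed + 1L)
  gp <- generate_genome(sp_pos, "pos_1")
  gn <- generate_genome(sp_neg, "neg_1")
  f <- file.path(dir, "two.fasta")
  write_fasta(list(gp$seq, gn$seq), f)
  list(fasta = f, pos = gp, neg = gn, sp_pos = sp_pos, sp_neg = sp_neg)
}
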