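# Shared fixtures: small synthetic studies built in code at test time.

# scaled-down study for module-level tests (the acceptance tests use the
# full default study where the check demands it)
tiny_params <- function(seed = 101, ...) {
  args <- list(seed = seed, n_samples = 4, reads_per_sample = 2500,
               n_hairpins = 14)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_params, args)
}

# write a synthetic reference to FASTA and build it through the real
# file-based entry point
build_ref_from_synth <- function(exp, extension = 4, mode = "per-mature") {
  d <- tempfile("synthref")
  dir.create(d)
  mf <- file.path(d, "mature.fa")
  hf <- file.path(d, "hairpin.fa")
  write_fasta(exp$reference$mature$id, exp$reference$mature$seq, mf)
  write_fasta(exp$reference$hairpin$id, exp$reference$hairpin$seq, hf)
  build_reference(mf, hf, extension = extension, mode = mode)
}

write_tmp_fasta <- function(ids, seqs) {
  f <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", seqs), f)
  f
}
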