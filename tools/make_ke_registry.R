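# Regenerates the packaged synthetic KE1-KE7 registry.
# Run from the package root:  Rscript tools/make_ke_registry.R
devtools::load_all(".", quiet = TRUE)
series <- generate_sequence_series(seed = 1L)  # package defaults
print(sapply(series, attr, "omega_achieved"))
write_charge_fasta(series, "inst/extdata/ke_synthetic.fasta")
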