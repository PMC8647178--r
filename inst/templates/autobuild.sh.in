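# Phenix AutoBuild: iterative model building, density modification, refinement
# adapt the invocation below to your installed Phenix version
phenix.autobuild data=@MTZ@ seq_file=@SEQ@ model="@PDB_IN@" \
  input_map_file=@MAP@ \
  && cp AutoBuild_run_1_/overall_best.pdb @PDB_OUT@
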