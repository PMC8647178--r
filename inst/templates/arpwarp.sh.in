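# ARP/wARP: automated model building with iterative refinement
# adapt the invocation below to your installed ARP/wARP version
auto_tracing.sh datafile @MTZ@ seqin @SEQ@ modelin "@PDB_IN@" \
  fp FP sigfp SIGFP phaselabin "PHIB FOM" \
  modelout @PDB_OUT@
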