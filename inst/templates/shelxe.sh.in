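# SHELXE: density modification and poly-Ala tracing
# adapt the invocation below to your installed SHELX version
shelxe @MTZ@ "@PDB_IN@" -a -q -s0.5 \
  && cp shelxe_trace.pdb @PDB_OUT@
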