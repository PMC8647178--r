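# Buccaneer: statistical chain tracing
# adapt the invocation below to your installed CCP4 version
cbuccaneer -mtzin @MTZ@ -seqin @SEQ@ -pdbin-mr "@PDB_IN@" \
  -colin-fo "FP,SIGFP" -colin-phifom "PHIB,FOM" \
  -cycles 5 -pdbout @PDB_OUT@
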