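# Parrot: density modification preconditioning of the starting map
# adapt the invocation below to your installed CCP4 version
cparrot -mtzin @MTZ@ -mapin @MAP_IN@ -cycles 3 -mapout @MAP_OUT@
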