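class,n_specimens
Plain,2
Simple,13
SimpleCrossoverILPS,16
SimpleCrossoverPSIL,7
ComplexNoCrossover,2
ComplexCrossover,12
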