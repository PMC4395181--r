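taxon,clementsian,gleasonian,quasi_clementsian,quasi_gleasonian,quasi_nested,random
algae,4,4,1,1,2,2
bacteria,1,0,0,0,4,1
invertebrates,3,1,0,2,3,3
macrophytes,2,0,3,1,0,2
vertebrates,1,0,1,0,2,0
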