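suffix	replacement
ations	ate
ation	ate
ized	ize
izing	ize
ies	y
ing	
ied	y
ed	
es	
s	
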