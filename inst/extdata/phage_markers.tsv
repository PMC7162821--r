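class	pattern
capsid	capsid
tail	tail
terminase	terminase
spike	spike
holin	holin
portal	portal
baseplate	baseplate
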