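type	key	value
stack	AU:AU	-0.93
stack	AU:UA	-1.10
stack	AU:GC	-2.24
stack	AU:CG	-2.08
stack	AU:GU	-1.00
stack	AU:UG	-1.00
stack	UA:AU	-1.33
stack	UA:UA	-0.93
stack	UA:GC	-2.35
stack	UA:CG	-2.11
stack	UA:GU	-1.00
stack	UA:UG	-1.00
stack	GC:AU	-2.11
stack	GC:UA	-2.08
stack	GC:GC	-3.26
stack	GC:CG	-2.36
stack	GC:GU	-1.00
stack	GC:UG	-1.00
stack	CG:AU	-2.35
stack	CG:UA	-2.24
stack	CG:GC	-3.42
stack	CG:CG	-3.26
stack	CG:GU	-1.00
stack	CG:UG	-1.00
stack	GU:AU	-1.00
stack	GU:UA	-1.00
stack	GU:GC	-1.00
stack	GU:CG	-1.00
stack	GU:GU	-1.00
stack	GU:UG	-1.00
stack	UG:AU	-1.00
stack	UG:UA	-1.00
stack	UG:GC	-1.00
stack	UG:CG	-1.00
stack	UG:GU	-1.00
stack	UG:UG	-1.00
hairpin	3	5.40
hairpin	4	5.60
hairpin	5	5.70
hairpin	6	5.40
hairpin	7	6.00
hairpin	8	5.50
hairpin	9	6.40
bulge	1	3.80
bulge	2	2.80
bulge	3	3.20
bulge	4	3.60
bulge	5	4.00
bulge	6	4.40
internal	2	1.50
internal	3	2.00
internal	4	2.50
internal	5	3.00
internal	6	3.50
multiloop	close	3.40
multiloop	branch	0.40
meta	max_interior	30
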