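# Published reference-gene suggestions per species and tissue (ordered).
species	tissue	gene1	gene2	gene3
piceifrons	head	RIBL5	Hsp70	EF2
piceifrons	thorax	RIBL5	Hsp70	GAPDH
americana	head	Act5C	EF2	NA
americana	thorax	RIBL5	EF2	NA
cubense	head	Act5C	Hsp70	NA
cubense	thorax	Hsp70	Ann	NA
nitens	head	Ann	Act5C	NA
nitens	thorax	Ann	Arm	NA
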