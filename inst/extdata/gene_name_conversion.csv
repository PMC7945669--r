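standard_name,variant
ND1,nad1
ND1,NADH1
ND1,NADH dehydrogenase subunit 1
ND1,NADH dehydrogenase 1
ND1,MT-ND1
ND1,NADH-1
ND2,nad2
ND2,NADH2
ND2,NADH dehydrogenase subunit 2
ND2,NADH dehydrogenase 2
ND2,MT-ND2
ND2,NADH-2
ND2,NADH dehydogenase subunit 2
ND3,nad3
ND3,NADH3
ND3,NADH dehydrogenase subunit 3
ND3,NADH dehydrogenase 3
ND3,MT-ND3
ND4,nad4
ND4,NADH4
ND4,NADH dehydrogenase subunit 4
ND4,NADH dehydrogenase 4
ND4,MT-ND4
ND4L,nad4L
ND4L,NADH4L
ND4L,NADH dehydrogenase subunit 4L
ND4L,NADH dehydrogenase 4L
ND4L,MT-ND4L
ND5,nad5
ND5,NADH5
ND5,NADH dehydrogenase subunit 5
ND5,NADH dehydrogenase 5
ND5,MT-ND5
ND6,nad6
ND6,NADH6
ND6,NADH dehydrogenase subunit 6
ND6,NADH dehydrogenase 6
ND6,MT-ND6
COX1,COI
COX1,CO1
COX1,COXI
COX1,cox 1
COX1,cytochrome c oxidase subunit 1
COX1,cytochrome c oxidase subunit I
COX1,cytochrome oxidase subunit 1
COX1,cytochrome oxidase subunit I
COX1,MT-CO1
COX2,COII
COX2,CO2
COX2,COXII
COX2,cytochrome c oxidase subunit 2
COX2,cytochrome c oxidase subunit II
COX2,cytochrome oxidase subunit 2
COX2,MT-CO2
COX3,COIII
COX3,CO3
COX3,COXIII
COX3,cytochrome c oxidase subunit 3
COX3,cytochrome c oxidase subunit III
COX3,cytochrome oxidase subunit 3
COX3,MT-CO3
ATP6,ATPase6
ATP6,ATPase 6
ATP6,ATP synthase 6
ATP6,ATP synthase F0 subunit 6
ATP6,atp6
ATP6,MT-ATP6
ATP8,ATPase8
ATP8,ATPase 8
ATP8,ATP synthase 8
ATP8,ATP synthase F0 subunit 8
ATP8,atp8
ATP8,MT-ATP8
CYTB,cytb
CYTB,cyt b
CYTB,cyt-b
CYTB,cob
CYTB,cytochrome b
CYTB,cytochrome-b
CYTB,MT-CYB
12S,12S rRNA
12S,12S ribosomal RNA
12S,s-rRNA
12S,rrnS
12S,small subunit ribosomal RNA
12S,MT-RNR1
16S,16S rRNA
16S,16S ribosomal RNA
16S,l-rRNA
16S,rrnL
16S,large subunit ribosomal RNA
16S,MT-RNR2
D-loop,Dloop
D-loop,control region
D-loop,CR
D-loop,mitochondrial control region
D-loop,D loop
tRNA-Phe,trnF
tRNA-Phe,tRNA Phe
tRNA-Pro,trnP
tRNA-Pro,tRNA Pro
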