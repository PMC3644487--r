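# Built-in restriction-enzyme catalog: common commercially available
# Type II endonucleases, REBASE recognition sequences (IUPAC codes).
# Format: NAME<tab>SITE  (one per line; '#' starts a comment)
AatII	GACGTC
AccI	GTMKAC
AflII	CTTAAG
AflIII	ACRYGT
AgeI	ACCGGT
AluI	AGCT
ApaI	GGGCCC
ApaLI	GTGCAC
ApoI	RAATTY
AscI	GGCGCGCC
AseI	ATTAAT
AvaI	CYCGRG
AvrII	CCTAGG
BamHI	GGATCC
BanII	GRGCYC
BclI	TGATCA
BglII	AGATCT
BsaI	GGTCTC
BsiWI	CGTACG
BsrGI	TGTACA
BstBI	TTCGAA
BstYI	RGATCY
ClaI	ATCGAT
DdeI	CTNAG
DraI	TTTAAA
EagI	CGGCCG
EcoRI	GAATTC
EcoRV	GATATC
FseI	GGCCGGCC
HaeIII	GGCC
HincII	GTYRAC
HindIII	AAGCTT
HinfI	GANTC
HpaI	GTTAAC
KpnI	GGTACC
MfeI	CAATTG
MluI	ACGCGT
MscI	TGGCCA
MseI	TTAA
NaeI	GCCGGC
NcoI	CCATGG
NdeI	CATATG
NheI	GCTAGC
NotI	GCGGCCGC
NruI	TCGCGA
NsiI	ATGCAT
NspI	RCATGY
PacI	TTAATTAA
PciI	ACATGT
PmeI	GTTTAAAC
PmlI	CACGTG
PstI	CTGCAG
PvuI	CGATCG
PvuII	CAGCTG
RsaI	GTAC
SacI	GAGCTC
SacII	CCGCGG
SalI	GTCGAC
SapI	GCTCTTC
ScaI	AGTACT
SmaI	CCCGGG
SnaBI	TACGTA
SpeI	ACTAGT
SphI	GCATGC
SspI	AATATT
StuI	AGGCCT
StyI	CCWWGG
SwaI	ATTTAAAT
TaqI	TCGA
XbaI	TCTAGA
XhoI	CTCGAG
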