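name,pct_inhibition,annotation
TIGOGENIN,100,p38 MAPK
IRIDIN,100,Unknown activity
TRIACETYLRESVERATROL,100,"P53, Notch"
ANDIROBIN,100,Unknown activity
MITOXANTHRONE HYDROCHLORIDE,96,"Antineoplastic, Topo II inhibitor"
DIHYDROFISSINOLIDE,90,Unknown activity
ADENINE,87,Vitamin B4
RESVERATROL,87,"Activates Notch-1, block Src/STAT3"
DIHYDRODEOXYGEDUNIN,83,Unknown activity
AKLAVINE HYDROCHLORIDE,80,"antibacterial, antineoplastic"
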