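term	canonical_id
Intrinsic Pathway for Apoptosis	cell_cycle
PTK6 Regulates Cell Cycle	cell_cycle
Interferon Signaling	immune
PI3K-Akt-mTOR	pi3k_akt
NRF2 pathway	nrf2
TGF-beta Signaling Pathway	tgf_beta
p53 signaling pathway	p53
regulation of intrinsic apoptotic signaling pathway	cell_cycle
PI3K-AKT-mTOR signaling pathway and therapeutic opportunities	pi3k_akt
EGF/EGFR Signaling Pathway	rtk_ras_mapk
Fc epsilon RI signaling pathway	immune
T cell receptor signaling pathway	immune
B cell receptor signaling pathway	immune
Canonical and Non-Canonical TGF-B signaling	tgf_beta
VEGFA-VEGFR2 Signaling Pathway	rtk_ras_mapk
NF-kB activation through FADD/RIP-1 pathway mediated by caspase-8 and -10	immune
Cytokine Signaling in Immune system	immune
MAPK Signaling Pathway	rtk_ras_mapk
intrinsic apoptotic signaling pathway	cell_cycle
IL-4 Signaling Pathway	immune
IL17 signaling pathway	immune
TCF dependent signaling in response to WNT	wnt
TNF signaling pathway	immune
Inflammatory Response Pathway	immune
Notch Signaling Pathway	notch
ErbB Signaling Pathway	rtk_ras_mapk
TP53 Regulates Transcription of Cell Cycle Genes	p53
Signaling by EGFR	rtk_ras_mapk
Apoptosis	cell_cycle
Wnt Signaling Pathway and Pluripotency	wnt
T-Cell Receptor and Co-stimulatory Signaling	immune
TNF alpha Signaling Pathway	immune
TGF-beta Receptor Signaling	tgf_beta
Cell Cycle, Mitotic	cell_cycle
Chemokine signaling pathway	immune
Signaling by NOTCH1 in Cancer	notch
PDGF Pathway	rtk_ras_mapk
RIG-I-like Receptor Signaling	immune
Interferon gamma signaling	immune
regulation of cell cycle	cell_cycle
regulation of apoptotic process	cell_cycle
Negative regulators of RIG-I/MDA5 signaling	immune
Pathways Regulating Hippo Signaling	hippo
Apoptosis-related network due to altered Notch3 in ovarian cancer	notch
Activated TLR4 signalling	immune
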