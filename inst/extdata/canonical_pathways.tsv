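canonical_id	pattern	categories	note
cell_cycle	cell cycle	proliferation_apoptosis	
cell_cycle	mitotic	proliferation_apoptosis	
cell_cycle	apoptosis	proliferation_apoptosis	
cell_cycle	apoptotic	proliferation_apoptosis	
p53	p53	proliferation_apoptosis	
nrf2	nrf2	proliferation_apoptosis	
nrf2	oxidative stress	proliferation_apoptosis	
pi3k_akt	pi3k	proliferation_apoptosis	
pi3k_akt	pi-3-kinase	proliferation_apoptosis	
pi3k_akt	akt	proliferation_apoptosis	
pi3k_akt	mtor	proliferation_apoptosis	
rtk_ras_mapk	mapk	proliferation_apoptosis	
rtk_ras_mapk	erbb	proliferation_apoptosis	
rtk_ras_mapk	egfr	proliferation_apoptosis	
rtk_ras_mapk	egf/egfr	proliferation_apoptosis	
rtk_ras_mapk	ras signaling	proliferation_apoptosis	
rtk_ras_mapk	ptk6	proliferation_apoptosis	
rtk_ras_mapk	vegf	angiogenesis	receptor tyrosine kinase driving vessel growth
rtk_ras_mapk	pdgf	angiogenesis	receptor tyrosine kinase driving vessel growth
tgf_beta	tgf	proliferation_apoptosis;metastasis_invasion	context-dependent: growth arrest/apoptosis vs EMT
wnt	wnt	proliferation_apoptosis;metastasis_invasion	
wnt	beta-catenin	proliferation_apoptosis;metastasis_invasion	
notch	notch	proliferation_apoptosis;metastasis_invasion	
hippo	hippo	proliferation_apoptosis;metastasis_invasion	
myc	myc	proliferation_apoptosis	
immune	interferon	proliferation_apoptosis	tumour microenvironment
immune	cytokine	proliferation_apoptosis	tumour microenvironment
immune	chemokine	proliferation_apoptosis	tumour microenvironment
immune	interleukin	proliferation_apoptosis	tumour microenvironment
immune	il17	proliferation_apoptosis	tumour microenvironment
immune	il-4	proliferation_apoptosis	tumour microenvironment
immune	tnf	proliferation_apoptosis	tumour microenvironment
immune	t cell receptor	proliferation_apoptosis	tumour microenvironment
immune	t-cell receptor	proliferation_apoptosis	tumour microenvironment
immune	b cell receptor	proliferation_apoptosis	tumour microenvironment
immune	b-cell receptor	proliferation_apoptosis	tumour microenvironment
immune	fc epsilon	proliferation_apoptosis	tumour microenvironment
immune	toll	proliferation_apoptosis	tumour microenvironment
immune	tlr	proliferation_apoptosis	tumour microenvironment
immune	rig-i	proliferation_apoptosis	tumour microenvironment
immune	nf-kb	proliferation_apoptosis	tumour microenvironment
immune	inflammatory	proliferation_apoptosis	tumour microenvironment
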