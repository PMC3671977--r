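# SYNTHETIC slim functional annotation of the 35-protein catalog.
# This table is a reconstruction assembled for profiling mechanics: term
# assignments follow each protein's well-known localization/function and the
# narrative summaries of the source study (e.g. 10 of the 11 ubiquitous
# proteins extracellular), but it is NOT authoritative Gene Ontology data
# and carries no GO identifiers or evidence codes.
accession	aspect	term
4505821	cellular_component	extracellular region
4505821	cellular_component	secretory granule
4505821	biological_process	biological regulation
4505821	biological_process	cell development
4506885	cellular_component	extracellular region
4506885	cellular_component	secretory granule
4506885	biological_process	biological regulation
4506885	biological_process	protein metabolic process
4502027	cellular_component	extracellular region
4502027	biological_process	transport
4502027	biological_process	biological regulation
54607120	cellular_component	extracellular region
54607120	biological_process	defense response
54607120	biological_process	transport
54607120	biological_process	biological regulation
54607120	biological_process	cell development
5453678	cellular_component	extracellular region
5453678	biological_process	transport
5453678	biological_process	biological regulation
5453678	biological_process	cell development
221316614	cellular_component	extracellular region
221316614	biological_process	biological regulation
221316614	biological_process	cell development
11386147	cellular_component	extracellular region
11386147	cellular_component	lysosome
11386147	cellular_component	vacuole
11386147	biological_process	biological regulation
11386147	biological_process	vesicle-mediated transport
11386147	biological_process	immune system process
4503143	cellular_component	lysosome
4503143	biological_process	protein metabolic process
4503143	biological_process	biological regulation
4503143	biological_process	cell development
4502173	cellular_component	extracellular region
4502173	cellular_component	secretory granule
4502173	biological_process	protein metabolic process
4502173	biological_process	biological regulation
4502173	biological_process	cell development
4502337	cellular_component	extracellular region
4502337	cellular_component	plasma membrane
4502337	biological_process	signal transduction
4502337	biological_process	biological regulation
42716297	cellular_component	extracellular region
42716297	cellular_component	cytosol
42716297	cellular_component	secretory granule
42716297	biological_process	signal transduction
42716297	biological_process	stress response
42716297	biological_process	biological regulation
42716297	biological_process	cell development
151301154	cellular_component	extracellular region
151301154	cellular_component	Golgi apparatus
151301154	biological_process	biological regulation
4503109	cellular_component	extracellular region
4503109	biological_process	protein metabolic process
4503109	biological_process	biological regulation
5031863	cellular_component	extracellular region
5031863	cellular_component	plasma membrane
5031863	biological_process	signal transduction
5031863	biological_process	immune system process
5031863	biological_process	biological regulation
38049014	cellular_component	extracellular region
38049014	cellular_component	secretory granule
38049014	biological_process	biological regulation
38049014	biological_process	protein metabolic process
6382064	cellular_component	extracellular region
6382064	cellular_component	lysosome
6382064	biological_process	protein metabolic process
6382064	biological_process	biological regulation
4503107	cellular_component	extracellular region
4503107	cellular_component	Golgi apparatus
4503107	biological_process	protein metabolic process
4503107	biological_process	biological regulation
4507509	cellular_component	extracellular region
4507509	cellular_component	Golgi apparatus
4507509	biological_process	protein metabolic process
4507509	biological_process	biological regulation
4757826	cellular_component	extracellular region
4757826	cellular_component	plasma membrane
4757826	cellular_component	protein complex
4757826	biological_process	immune system process
4757826	biological_process	signal transduction
4757826	biological_process	defense response
31543380	cellular_component	cytosol
31543380	cellular_component	nucleus
31543380	biological_process	stress response
31543380	biological_process	defense response
31543380	biological_process	biological regulation
56676397	cellular_component	nucleus
56676397	cellular_component	cytosol
56676397	biological_process	biological regulation
167857790	cellular_component	extracellular region
167857790	biological_process	immune system process
167857790	biological_process	defense response
50363217	cellular_component	extracellular region
50363217	biological_process	protein metabolic process
50363217	biological_process	biological regulation
4557871	cellular_component	extracellular region
4557871	cellular_component	endosome
4557871	biological_process	transport
4557871	biological_process	vesicle-mediated transport
4557871	biological_process	stress response
4507065	cellular_component	extracellular region
4507065	biological_process	protein metabolic process
4507065	biological_process	defense response
4506713	cellular_component	cytosol
4506713	cellular_component	ribosome
4506713	cellular_component	nucleus
4506713	biological_process	protein metabolic process
4506713	biological_process	biological regulation
104487006	cellular_component	plasma membrane
104487006	cellular_component	nucleus
104487006	biological_process	signal transduction
104487006	biological_process	biological regulation
25121982	cellular_component	extracellular region
25121982	biological_process	biological regulation
25121982	biological_process	cell development
32171249	cellular_component	extracellular region
32171249	cellular_component	nucleus
32171249	biological_process	transport
32171249	biological_process	vesicle-mediated transport
4503139	cellular_component	lysosome
4503139	cellular_component	vacuole
4503139	biological_process	protein metabolic process
4503139	biological_process	vesicle-mediated transport
19923082	cellular_component	extracellular region
19923082	cellular_component	endosome
19923082	cellular_component	nucleus
19923082	biological_process	biological regulation
4505529	cellular_component	extracellular region
4505529	biological_process	immune system process
4505529	biological_process	defense response
110735433	cellular_component	plasma membrane
110735433	cellular_component	endosome
110735433	cellular_component	nucleus
110735433	biological_process	immune system process
4503009	cellular_component	extracellular region
4503009	cellular_component	Golgi apparatus
4503009	biological_process	protein metabolic process
4503009	biological_process	biological regulation
47132551	cellular_component	extracellular region
47132551	cellular_component	protein complex
47132551	biological_process	cell development
47132551	biological_process	biological regulation
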