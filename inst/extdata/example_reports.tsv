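report_id	drugs	ades
r0001	warfarin|tetracycline	delirium
r0002	warfarin	
r0003	tetracycline|prednisone	
r0004	warfarin|tetracycline|prednisone	delirium|neuropathy
r0005	prednisone	neuropathy
r0006	warfarin|prednisone	
r0007	tetracycline	delirium
r0008	warfarin|tetracycline	
r0009	prednisone|gemcitabine	
r0010	gemcitabine	neuropathy
r0011	warfarin|tetracycline	delirium
r0012	gemcitabine|prednisone	delirium
r0013	warfarin	
r0014	tetracycline	
r0015	warfarin|gemcitabine	neuropathy
r0016	prednisone	
r0017	warfarin|tetracycline	
r0018	tetracycline|gemcitabine	
r0019	warfarin	delirium
r0020	prednisone|tetracycline	neuropathy
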