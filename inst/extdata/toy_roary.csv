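"Gene","Non-unique Gene name","Annotation","No. isolates","No. sequences","Avg sequences per isolate","Genome Fragment","Order within Fragment","Accessory Fragment","Accessory Order with Fragment","QC","Min group size nuc","Max group size nuc","Avg group size nuc","gA","gB","gC"
"group_1","","hypothetical, protein","3","3","1","1","1","","","","300","312","305","gA_001","gB_004","gC_003"
"group_2","dnaA","chromosomal replication initiator","2","2","1","1","2","","","","1350","1353","1351.5","gA_002","","gC_001"
"group_3","","transposase","1","2","2","","","1","1","","900","903","901.5","","gB_001",""
"group_4","","ABC transporter","2","2","1","1","3","","","","600","600","600","gA_003","gB_002",""
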