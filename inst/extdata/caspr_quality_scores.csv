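# Quality scores for refining comparative models TMR01, TMR04 and TMR07
# by five refinement methods; RMSD-type scores are lower-better, all
# other scores higher-better.  The None row is the unrefined model.
model,method,score,value,orientation
"TMR01","None","sseRMSD",1.3,"lower_better"
"TMR01","None","CaRMSD",6.1,"lower_better"
"TMR01","None","GDT-TS",0.772,"higher_better"
"TMR01","None","GDT-HA",0.593,"higher_better"
"TMR01","None","GDC-all",0.491,"higher_better"
"TMR01","None","RPF9",0.69,"higher_better"
"TMR01","None","LDDT15",0.631,"higher_better"
"TMR01","None","SG2n6",0.495,"higher_better"
"TMR01","None","CAD",0.609,"higher_better"
"TMR01","RAPDF/HB_EM","sseRMSD",0.9,"lower_better"
"TMR01","RAPDF/HB_EM","CaRMSD",NA,"lower_better"
"TMR01","RAPDF/HB_EM","GDT-TS",NA,"higher_better"
"TMR01","RAPDF/HB_EM","GDT-HA",NA,"higher_better"
"TMR01","RAPDF/HB_EM","GDC-all",NA,"higher_better"
"TMR01","RAPDF/HB_EM","RPF9",NA,"higher_better"
"TMR01","RAPDF/HB_EM","LDDT15",NA,"higher_better"
"TMR01","RAPDF/HB_EM","SG2n6",NA,"higher_better"
"TMR01","RAPDF/HB_EM","CAD",NA,"higher_better"
"TMR01","GBSW","sseRMSD",NA,"lower_better"
"TMR01","GBSW","CaRMSD",3.9,"lower_better"
"TMR01","GBSW","GDT-TS",0.835,"higher_better"
"TMR01","GBSW","GDT-HA",NA,"higher_better"
"TMR01","GBSW","GDC-all",NA,"higher_better"
"TMR01","GBSW","RPF9",NA,"higher_better"
"TMR01","GBSW","LDDT15",NA,"higher_better"
"TMR01","GBSW","SG2n6",NA,"higher_better"
"TMR01","GBSW","CAD",NA,"higher_better"
"TMR01","FF12MC","sseRMSD",0.7,"lower_better"
"TMR01","FF12MC","CaRMSD",1.4,"lower_better"
"TMR01","FF12MC","GDT-TS",0.92,"higher_better"
"TMR01","FF12MC","GDT-HA",0.797,"higher_better"
"TMR01","FF12MC","GDC-all",0.82,"higher_better"
"TMR01","FF12MC","RPF9",0.851,"higher_better"
"TMR01","FF12MC","LDDT15",0.791,"higher_better"
"TMR01","FF12MC","SG2n6",0.766,"higher_better"
"TMR01","FF12MC","CAD",0.693,"higher_better"
"TMR01","FF14SBlm","sseRMSD",1.1,"lower_better"
"TMR01","FF14SBlm","CaRMSD",3,"lower_better"
"TMR01","FF14SBlm","GDT-TS",0.849,"higher_better"
"TMR01","FF14SBlm","GDT-HA",0.717,"higher_better"
"TMR01","FF14SBlm","GDC-all",0.689,"higher_better"
"TMR01","FF14SBlm","RPF9",0.805,"higher_better"
"TMR01","FF14SBlm","LDDT15",0.75,"higher_better"
"TMR01","FF14SBlm","SG2n6",0.663,"higher_better"
"TMR01","FF14SBlm","CAD",0.656,"higher_better"
"TMR01","FF96lm","sseRMSD",1.4,"lower_better"
"TMR01","FF96lm","CaRMSD",3.9,"lower_better"
"TMR01","FF96lm","GDT-TS",0.854,"higher_better"
"TMR01","FF96lm","GDT-HA",0.712,"higher_better"
"TMR01","FF96lm","GDC-all",0.653,"higher_better"
"TMR01","FF96lm","RPF9",0.776,"higher_better"
"TMR01","FF96lm","LDDT15",0.723,"higher_better"
"TMR01","FF96lm","SG2n6",0.629,"higher_better"
"TMR01","FF96lm","CAD",0.642,"higher_better"
"TMR04","None","sseRMSD",1.8,"lower_better"
"TMR04","None","CaRMSD",2.2,"lower_better"
"TMR04","None","GDT-TS",0.743,"higher_better"
"TMR04","None","GDT-HA",0.543,"higher_better"
"TMR04","None","GDC-all",0.637,"higher_better"
"TMR04","None","RPF9",0.667,"higher_better"
"TMR04","None","LDDT15",0.603,"higher_better"
"TMR04","None","SG2n6",0.3,"higher_better"
"TMR04","None","CAD",0.626,"higher_better"
"TMR04","RAPDF/HB_EM","sseRMSD",0.8,"lower_better"
"TMR04","RAPDF/HB_EM","CaRMSD",NA,"lower_better"
"TMR04","RAPDF/HB_EM","GDT-TS",NA,"higher_better"
"TMR04","RAPDF/HB_EM","GDT-HA",NA,"higher_better"
"TMR04","RAPDF/HB_EM","GDC-all",NA,"higher_better"
"TMR04","RAPDF/HB_EM","RPF9",NA,"higher_better"
"TMR04","RAPDF/HB_EM","LDDT15",NA,"higher_better"
"TMR04","RAPDF/HB_EM","SG2n6",NA,"higher_better"
"TMR04","RAPDF/HB_EM","CAD",NA,"higher_better"
"TMR04","GBSW","sseRMSD",NA,"lower_better"
"TMR04","GBSW","CaRMSD",1.6,"lower_better"
"TMR04","GBSW","GDT-TS",0.9,"higher_better"
"TMR04","GBSW","GDT-HA",NA,"higher_better"
"TMR04","GBSW","GDC-all",NA,"higher_better"
"TMR04","GBSW","RPF9",NA,"higher_better"
"TMR04","GBSW","LDDT15",NA,"higher_better"
"TMR04","GBSW","SG2n6",NA,"higher_better"
"TMR04","GBSW","CAD",NA,"higher_better"
"TMR04","FF12MC","sseRMSD",0.6,"lower_better"
"TMR04","FF12MC","CaRMSD",1.5,"lower_better"
"TMR04","FF12MC","GDT-TS",0.932,"higher_better"
"TMR04","FF12MC","GDT-HA",0.811,"higher_better"
"TMR04","FF12MC","GDC-all",0.793,"higher_better"
"TMR04","FF12MC","RPF9",0.8,"higher_better"
"TMR04","FF12MC","LDDT15",0.762,"higher_better"
"TMR04","FF12MC","SG2n6",0.831,"higher_better"
"TMR04","FF12MC","CAD",0.687,"higher_better"
"TMR04","FF14SBlm","sseRMSD",0.8,"lower_better"
"TMR04","FF14SBlm","CaRMSD",1.1,"lower_better"
"TMR04","FF14SBlm","GDT-TS",0.939,"higher_better"
"TMR04","FF14SBlm","GDT-HA",0.818,"higher_better"
"TMR04","FF14SBlm","GDC-all",0.838,"higher_better"
"TMR04","FF14SBlm","RPF9",0.805,"higher_better"
"TMR04","FF14SBlm","LDDT15",0.776,"higher_better"
"TMR04","FF14SBlm","SG2n6",0.802,"higher_better"
"TMR04","FF14SBlm","CAD",0.683,"higher_better"
"TMR04","FF96lm","sseRMSD",0.7,"lower_better"
"TMR04","FF96lm","CaRMSD",1.6,"lower_better"
"TMR04","FF96lm","GDT-TS",0.921,"higher_better"
"TMR04","FF96lm","GDT-HA",0.771,"higher_better"
"TMR04","FF96lm","GDC-all",0.776,"higher_better"
"TMR04","FF96lm","RPF9",0.777,"higher_better"
"TMR04","FF96lm","LDDT15",0.744,"higher_better"
"TMR04","FF96lm","SG2n6",0.79,"higher_better"
"TMR04","FF96lm","CAD",0.664,"higher_better"
"TMR07","None","sseRMSD",1.9,"lower_better"
"TMR07","None","CaRMSD",2.2,"lower_better"
"TMR07","None","GDT-TS",0.766,"higher_better"
"TMR07","None","GDT-HA",0.556,"higher_better"
"TMR07","None","GDC-all",0.668,"higher_better"
"TMR07","None","RPF9",0.686,"higher_better"
"TMR07","None","LDDT15",0.618,"higher_better"
"TMR07","None","SG2n6",0.383,"higher_better"
"TMR07","None","CAD",0.59,"higher_better"
"TMR07","RAPDF/HB_EM","sseRMSD",2.1,"lower_better"
"TMR07","RAPDF/HB_EM","CaRMSD",NA,"lower_better"
"TMR07","RAPDF/HB_EM","GDT-TS",NA,"higher_better"
"TMR07","RAPDF/HB_EM","GDT-HA",NA,"higher_better"
"TMR07","RAPDF/HB_EM","GDC-all",NA,"higher_better"
"TMR07","RAPDF/HB_EM","RPF9",NA,"higher_better"
"TMR07","RAPDF/HB_EM","LDDT15",NA,"higher_better"
"TMR07","RAPDF/HB_EM","SG2n6",NA,"higher_better"
"TMR07","RAPDF/HB_EM","CAD",NA,"higher_better"
"TMR07","GBSW","sseRMSD",NA,"lower_better"
"TMR07","GBSW","CaRMSD",2.7,"lower_better"
"TMR07","GBSW","GDT-TS",0.81,"higher_better"
"TMR07","GBSW","GDT-HA",NA,"higher_better"
"TMR07","GBSW","GDC-all",NA,"higher_better"
"TMR07","GBSW","RPF9",NA,"higher_better"
"TMR07","GBSW","LDDT15",NA,"higher_better"
"TMR07","GBSW","SG2n6",NA,"higher_better"
"TMR07","GBSW","CAD",NA,"higher_better"
"TMR07","FF12MC","sseRMSD",1.5,"lower_better"
"TMR07","FF12MC","CaRMSD",2.4,"lower_better"
"TMR07","FF12MC","GDT-TS",0.846,"higher_better"
"TMR07","FF12MC","GDT-HA",0.68,"higher_better"
"TMR07","FF12MC","GDC-all",0.732,"higher_better"
"TMR07","FF12MC","RPF9",0.815,"higher_better"
"TMR07","FF12MC","LDDT15",0.762,"higher_better"
"TMR07","FF12MC","SG2n6",0.777,"higher_better"
"TMR07","FF12MC","CAD",0.694,"higher_better"
"TMR07","FF14SBlm","sseRMSD",1.2,"lower_better"
"TMR07","FF14SBlm","CaRMSD",1.8,"lower_better"
"TMR07","FF14SBlm","GDT-TS",0.832,"higher_better"
"TMR07","FF14SBlm","GDT-HA",0.654,"higher_better"
"TMR07","FF14SBlm","GDC-all",0.753,"higher_better"
"TMR07","FF14SBlm","RPF9",0.762,"higher_better"
"TMR07","FF14SBlm","LDDT15",0.713,"higher_better"
"TMR07","FF14SBlm","SG2n6",0.62,"higher_better"
"TMR07","FF14SBlm","CAD",0.689,"higher_better"
"TMR07","FF96lm","sseRMSD",1.6,"lower_better"
"TMR07","FF96lm","CaRMSD",2.7,"lower_better"
"TMR07","FF96lm","GDT-TS",0.872,"higher_better"
"TMR07","FF96lm","GDT-HA",0.71,"higher_better"
"TMR07","FF96lm","GDC-all",0.719,"higher_better"
"TMR07","FF96lm","RPF9",0.793,"higher_better"
"TMR07","FF96lm","LDDT15",0.765,"higher_better"
"TMR07","FF96lm","SG2n6",0.724,"higher_better"
"TMR07","FF96lm","CAD",0.711,"higher_better"
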