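group,replicate_id,method,label,plasmid_length_bp,amplicon_length_bp,template_mass_ng,output_mass_ng,sucrose_cfu,sucrose_dilution,sucrose_fraction,plain_cfu,plain_dilution,plain_fraction,nc_sucrose_cfu,nc_plain_cfu
MBI,r1,in_vivo,MBI,5000,5000,,5000,1,1,1,450,1000,1,0,0
MBI,r2,in_vivo,MBI,5000,5000,,4600,2,1,1,520,1000,1,1,0
MBI,r3,in_vivo,MBI,5000,5000,,5200,0,1,1,480,1000,1,0,1
Q5,r1,pcr,Q5,5000,2000,10,5000,35,1,1,300,1000,1,0,0
Q5,r2,pcr,Q5,5000,2000,10,4800,42,1,1,280,1000,1,2,0
Q5,r3,pcr,Q5,5000,2000,10,5100,28,1,1,310,1000,1,0,0
Phi29,r1,rca,Phi29,5000,5000,10,5000,210,10,1,260,1000,1,1,0
Phi29,r2,rca,Phi29,5000,5000,10,5100,190,10,1,240,1000,1,0,1
Phi29,r3,rca,Phi29,5000,5000,10,4900,240,10,1,250,1000,1,0,0
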