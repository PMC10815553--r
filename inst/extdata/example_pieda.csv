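complex_id,ligand_id,class,residue_id,residue_name,pie,e_es,e_ex,e_ct,e_disp,dg_solv,min_dist
AN1,lig_AN1,antagonist,332,D,-98.6,-104.2,12.5,-4.1,-5.3,2.5,2.7
AN1,lig_AN1,antagonist,336,C,-4.8,-3.1,2.2,-1.2,-3.4,0.7,3.4
AN1,lig_AN1,antagonist,546,S,2.6,1.4,4.8,-0.9,-2.9,0.2,4.1
AN1,lig_AN1,antagonist,648,W,-6.2,-2.0,3.5,-1.8,-6.5,0.6,3.6
AN1,lig_AN1,antagonist,739,T,-1.9,-0.8,1.1,-0.4,-2.1,0.3,4.3
AN1,lig_AN1,antagonist,543,S,-0.2,-0.1,0.1,-0.1,-0.2,0.1,6.8
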