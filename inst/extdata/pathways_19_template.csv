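pathway,gene,role
Wnt/Wingless,wg,ligand
Wnt/Wingless,fz,receptor
FGF,ths,ligand
FGF,pyr,ligand
FGF,htl,receptor
Hedgehog,hh,ligand
Hedgehog,ptc,receptor
Hedgehog,smo,receptor
PDGF/VEGF,Pvf1,ligand
PDGF/VEGF,Pvr,receptor
JAK-STAT,upd1,ligand
JAK-STAT,dome,receptor
activin,Actbeta,ligand
activin,babo,receptor
BMP,dpp,ligand
BMP,tkv,receptor
Fat-Ds,ds,ligand
Fat-Ds,ft,receptor
Slit-Robo,sli,ligand
Slit-Robo,robo2,receptor
ephrin,Ephrin,ligand
ephrin,Eph,receptor
toll/toll-like,spz,ligand
toll/toll-like,Toll-7,receptor
semaphorin,Sema1a,ligand
semaphorin,PlexA,receptor
Notch,Dl,ligand
Notch,N,receptor
insulin-like,Ilp8,ligand
insulin-like,InR,receptor
fog,fog,ligand
fog,mist,receptor
torso,trk,ligand
torso,tor,receptor
miple,mple,ligand
miple,Alk,receptor
EGFR,vn,ligand
EGFR,Egfr,receptor
TNF,egr,ligand
TNF,grnd,receptor
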