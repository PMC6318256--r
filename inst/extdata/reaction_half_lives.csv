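parent,product,kind,half_life_h
IBU,IBAP,photo,200
IBU,other,photo,50
IBAP,other,photo,21
IBU,IBU-CBX,bio,70
IBU,IBU-2OH,bio,35
IBU,other,bio,7
IBU-CBX,other,bio,8
IBU-2OH,other,bio,7
DCF,CPAB,photo,44
DCF,other,photo,4.4
CPAB,other,photo,4.0
CPAB,other,bio,9.825
DCF,5HDQI,bio,92
DCF,other,bio,11
5HDQI,other,bio,13
CBZ,AI,photo,10000
CBZ,AO,photo,100000
CBZ,other,photo,1000
AI,other,photo,450
AO,other,photo,450
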