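stage,amp_lo,amp_hi,dur_lo,dur_hi,isi_lo,isi_hi,rate_lo,rate_hi,delta_lo,delta_hi,theta_lo,theta_hi,alpha_lo,alpha_hi,sigma_lo,sigma_hi,beta_lo,beta_hi,gamma_lo,gamma_hi,act_lo,act_hi,behavior
1,200,600,100,200,400,1400,20,35,8,12,4,7,0.7,1.5,0.3,0.9,0.2,0.5,0.4,0.8,0,0,"Freezing, Staring"
2,200,1500,100,400,450,1500,40,60,25,50,5,15,3,5,1,3,1,3,1,2,0,0,"Hunched rocking with stiff tail"
HFT,300,1000,20,40,25,60,120,200,5,10,4,8,10,20,8,16,8,15,15,90,0,0,"No specific phenotypic correlate"
3A,300,700,50,150,100,600,40,60,10,15,6,12,8,15,8,13,6,12,15,70,0,8,"Rearing, forelimbs lifted"
3B,400,900,200,500,180,320,30,60,10,20,15,30,8,14,5,9,10,20,18,90,20,120,"Forelimbs clonus, raised tail"
4,400,700,200,400,200,800,30,70,5,20,15,20,5,10,4,8,8,15,15,50,20,80,"Rearing and falling"
5,300,700,50,200,50,200,80,140,8,15,5,15,4,8,3,7,5,12,8,30,30,60,"Generalized with forelimb and hind limb clonus"
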