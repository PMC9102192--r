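factor,level,AT,BA,CL,ME,cluster1,cluster2
gender,F,4,3,4,3,9,5
gender,M,14,8,10,9,30,11
location,floor of the mouth,0,1,1,1,2,1
location,hypopharynx,1,0,3,2,4,2
location,larynx,0,5,9,2,12,4
location,oral cavity,0,1,0,0,0,1
location,oropharynx,17,2,1,4,19,5
location,tongue,0,2,0,3,2,3
p16,p16 neg.,0,10,14,11,23,12
p16,p16 pos.,18,1,0,1,16,4
pN,<2,12,9,12,4,26,11
pN,>2,6,2,2,8,13,5
stage,I-II,16,5,3,4,20,8
stage,III-IV,2,6,11,8,19,8
smoking,0,14,0,0,4,14,4
smoking,1,4,11,14,8,25,12
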