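condition,marker,n_scored,n_affected
Klf2MO,zic1,74,67
Klf17MO,zic1,77,68
Klf2MO,pax3,65,56
Klf17MO,pax3,83,69
Klf2MO,msx1,60,45
Klf17MO,msx1,60,51
Klf2MO,snai2,166,128
Klf17MO,snai2,177,121
Klf2MO,foxd3,106,75
Klf17MO,foxd3,136,100
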