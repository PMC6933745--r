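service,sector,mpce_class,share_pct
IP,rural,P,9.90
IP,rural,LM,27.84
IP,rural,UM,26.63
IP,rural,R,35.63
IP,urban,P,21.05
IP,urban,LM,11.69
IP,urban,UM,30.15
IP,urban,R,37.11
IP,combine,P,16.09
IP,combine,LM,18.88
IP,combine,UM,28.58
IP,combine,R,36.45
OP,rural,P,40.61
OP,rural,LM,16.24
OP,rural,UM,15.57
OP,rural,R,27.59
OP,urban,P,18.28
OP,urban,LM,26.81
OP,urban,UM,17.32
OP,urban,R,37.59
OP,combine,P,28.55
OP,combine,LM,21.95
OP,combine,UM,16.51
OP,combine,R,32.99
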