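accession,morphological_id,westing,northing,depth
PH15596a,Rodentia,14,4,126
PH14514,Rodentia,15,6,125
PH9232,Rodentia,15,5,115
PH2963,Rodentia,13,3,109
PH6368,Apodemus sylvaticus,8,1,flowstone
PH4826,Indeterminate microvertebrate,7,9,flowstone
PH4845c,Rodentia,6,9,32
PH4845d,Rodentia,6,9,32
PH4522,Rodentia,5,9,35
PH4186a,Indeterminate microvertebrate,7,2,53
PH4429,Rodentia,13,2,94
PH4036a,Indeterminate microvertebrate (not bat),3,8,36
PH4036b,Indeterminate microvertebrate (not bat),3,8,36
PH4036c,Indeterminate microvertebrate (not bat),3,8,36
PH4036d,Indeterminate microvertebrate (not bat),3,8,36
PH6578b,Indeterminate mammal,15,5,109
PH2904c,Rodentia,8,1,flowstone
PH2904i,Rodentia,8,1,flowstone
PH2904j,Rodentia,8,1,flowstone
PH2904n,Rodentia,8,1,flowstone
PH2904p,Rodentia,8,1,flowstone
PH2837,Rodentia,15,5,107
PH2782,Indeterminate flake,4,14,28
PH2789,Rodentia,5,11,29
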