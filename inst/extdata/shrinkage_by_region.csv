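species,region,specimen,percent
Chiloscyllium punctatum,OBs,CP2,13.20
Chiloscyllium punctatum,OBs,CP3,7.61
Chiloscyllium punctatum,OBs,CP4,21.48
Chiloscyllium punctatum,Tel,CP2,11.04
Chiloscyllium punctatum,Tel,CP3,11.89
Chiloscyllium punctatum,Tel,CP4,14.63
Chiloscyllium punctatum,Cer,CP2,12.74
Chiloscyllium punctatum,Cer,CP3,12.01
Chiloscyllium punctatum,Cer,CP4,7.44
Chiloscyllium punctatum,Med,CP2,18.79
Chiloscyllium punctatum,Med,CP3,10.24
Chiloscyllium punctatum,Med,CP4,21.36
Carassius auratus,OBs,CA2,11.61
Carassius auratus,OBs,CA3,9.13
Carassius auratus,OBs,CA4,5.75
Carassius auratus,Tel,CA2,14.62
Carassius auratus,Tel,CA3,17.26
Carassius auratus,Tel,CA4,27.76
Carassius auratus,Cer,CA2,24.90
Carassius auratus,Cer,CA3,25.57
Carassius auratus,Cer,CA4,20.13
Carassius auratus,Med,CA2,13.68
Carassius auratus,Med,CA3,16.39
Carassius auratus,Med,CA4,26.42
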