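plant_id,day,n_branches,primary_length_cm,mean_lateral_length_cm
p1,5,13,2.41836208030048,0.194569920039694
p1,10,23,4.54430040302919,0.391286372080508
p1,15,30,6.41317429452067,0.605971427678459
p2,5,10,2.04292854226763,0.17911122402781
p2,10,22,3.87717923309467,0.373504179055922
p2,15,30,5.52406776942348,0.625704235716809
p3,5,12,2.45431656942933,0.188328184854664
p3,10,23,4.60744964770989,0.387467440055722
p3,15,35,6.49635921647994,0.56580148529183
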