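city,district,year,month,day,hour,ta,tmrt,v,rh,pet_reference,accident_type
Seoul,Gangbuk-gu,2009,1,2,9,-6.2,5.3,1.9,64,-9.5,fall
Seoul,Jung-gu,2009,1,2,9,-6.2,5.3,1.9,64,-9.5,traffic accident
Seoul,Gangseo-gu,2015,11,1,13,0.9,22.4,4.7,50,-2.5,fall
Seoul,Gangseo-gu,2015,11,1,15,2.3,20.3,4.3,41,-1.3,be hit
Cheongju,Sangdang-gu,2010,12,1,10,-1,17.2,4.5,77,-5,fall
Incheon,Nam-gu,2010,12,1,10,-4.5,12.4,7.6,57,-10.5,fall beneath
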