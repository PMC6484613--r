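variable,level,arm,num,den,printed_pct
gland_volume,missing,surgery,1318,3769,35.0
gland_volume,missing,radiotherapy,256,775,33.0
psa,missing,surgery,4,3769,0.1
cci,0,surgery,2178,3759,57.7
cci,1,surgery,330,3759,8.8
cci,2,surgery,268,3759,7.1
cci,3+,surgery,77,3759,2.0
cci,missing,surgery,916,3759,24.4
cci,0,radiotherapy,421,775,54.3
cci,1,radiotherapy,197,775,25.4
cci,2,radiotherapy,86,775,11.1
cci,3+,radiotherapy,59,775,7.6
cci,missing,radiotherapy,12,775,1.5
gleason,5/6,surgery,1798,3769,47.7
gleason,7=3+4,surgery,1288,3769,34.2
gleason,7=4+3,surgery,394,3769,10.5
gleason,8,surgery,164,3769,4.4
gleason,9/10,surgery,123,3769,3.3
gleason,missing,surgery,2,3769,0.1
gleason,5/6,radiotherapy,240,775,31.0
gleason,7=3+4,radiotherapy,225,775,29.0
gleason,7=4+3,radiotherapy,127,775,16.4
gleason,8,radiotherapy,81,775,10.5
gleason,9/10,radiotherapy,82,775,10.6
gleason,missing,radiotherapy,20,775,2.6
pni,present,surgery,840,3769,22.3
pni,missing,surgery,30,3769,0.8
pni,present,radiotherapy,268,775,34.6
pni,missing,radiotherapy,64,775,8.3
ct,1,surgery,2679,3769,71.1
ct,2,surgery,1062,3769,28.2
ct,3,surgery,19,3769,0.5
ct,missing,surgery,9,3769,0.2
ct,1,radiotherapy,438,775,56.5
ct,2,radiotherapy,292,775,37.7
ct,3,radiotherapy,41,775,5.3
ct,missing,radiotherapy,4,775,0.5
race,White,surgery,2684,3769,71.2
race,AfricanAmerican,surgery,170,3769,4.5
race,Other,surgery,30,3769,0.8
race,missing,surgery,885,3769,23.5
race,White,radiotherapy,674,775,87.0
race,AfricanAmerican,radiotherapy,75,775,9.7
race,Other,radiotherapy,6,775,0.8
race,missing,radiotherapy,20,775,2.6
tx_year,1996-2000,surgery,998,3769,26.5
tx_year,2001-2006,surgery,1202,3769,31.9
tx_year,2007-2013,surgery,1569,3769,41.6
tx_year,1996-2000,radiotherapy,207,775,26.7
tx_year,2001-2006,radiotherapy,376,775,48.5
tx_year,2007-2013,radiotherapy,192,775,24.8
neoadjuvant,yes,surgery,211,3769,5.6
neoadjuvant,yes,radiotherapy,273,775,35.2
cf,event,surgery,102,3769,2.7
cf,event,radiotherapy,55,775,7.1
death,event,surgery,270,3769,7.2
death,event,radiotherapy,198,775,25.6
death_after_cf,event,surgery,53,3769,1.4
death_after_cf,event,radiotherapy,37,775,4.8
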