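variable,category,units,lo,hi,staleness_h,fallback,fallback_source,ref_value,ref_sd
heart_rate,vital,bpm,20,300,4,none,,86,14
sbp_inv,vital,mmHg,30,300,4,nibp_to_ibp,sbp_ninv,118,20
dbp_inv,vital,mmHg,10,200,4,nibp_to_ibp,dbp_ninv,62,12
map_inv,vital,mmHg,20,250,4,nibp_to_ibp,map_ninv,80,14
sbp_ninv,vital,mmHg,30,300,4,none,,120,20
dbp_ninv,vital,mmHg,10,200,4,none,,64,12
map_ninv,vital,mmHg,20,250,4,none,,82,14
resp_rate,vital,breaths/min,4,80,4,none,,18,4
spo2,vital,%,50,100,4,none,,97,1.5
temperature,vital,degC,30,43,4,none,,36.8,0.5
cvp,vital,mmHg,-5,50,4,none,,9,4
glucose,lab,mg/dL,20,1000,48,none,,150,40
bun,lab,mg/dL,1,200,48,none,,24,10
creatinine,lab,mg/dL,0.1,30,48,none,,1.3,0.6
ast,lab,U/L,5,5000,48,none,,45,22
bilirubin,lab,mg/dL,0.05,60,48,none,,1,0.5
hemoglobin,lab,g/dL,2,25,48,none,,11,2
hematocrit,lab,%,9,75,48,none,,33,5
platelets,lab,1e3/uL,1,2000,48,none,,200,80
wbc,lab,1e3/uL,0.1,200,48,none,,11,4
sodium,lab,mmol/L,100,190,48,none,,139,4
potassium,lab,mmol/L,1,12,48,none,,4,0.5
bicarbonate,blood_gas,mmol/L,5,60,48,none,,24,4
lactate,blood_gas,mmol/L,0.1,30,48,none,,1.9,0.8
ph,blood_gas,pH,6.5,8,48,none,,7.38,0.06
pao2,blood_gas,mmHg,20,700,48,none,,98,25
paco2,blood_gas,mmHg,5,250,48,none,,40,8
fio2,ventilation,fraction,0.15,1,8,fio2_room_air,,0.4,0.1
peak_airway_pressure,ventilation,cmH2O,1,80,8,none,,22,5
mean_airway_pressure,ventilation,cmH2O,0.5,50,8,none,,12,3
peep,ventilation,cmH2O,0,25,8,none,,6,2
tidal_volume,ventilation,mL,50,2000,8,none,,450,80
minute_ventilation,ventilation,L/min,0.5,50,8,none,,8,2
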