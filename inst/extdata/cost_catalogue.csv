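code,label,category,unit_cost
surgery,Surgery,procedure,6269.20
hemofilter_kit,Hemofilter kit,procedure,173.82
mech_vent_icu,Mechanical ventilation at ICU (day),procedure,460.00
lab_profile,Laboratory profile,test,85.96
ecg,Electrocardiogram,test,20.37
echo,Echocardiogram,test,120.36
amiodarone_tab,Amiodarone prophylaxis (tablet),medication,0.11
amiodarone_iv,Amiodarone 150 mg (IV ampoule),medication,0.25
furosemide_iv,Furosemide 20 mg (IV ampoule),medication,0.13
atorvastatin,Atorvastatin 20 mg (tablet),medication,0.07
bisoprolol,Bisoprolol 5 mg (tablet),medication,0.08
asa,Acetylsalicylic acid 100 mg (tablet),medication,0.03
dalteparin,"Dalteparin 5000 IU (SC, prefilled syringe)",medication,0.31
acetaminophen_iv,Acetaminophen 1 g IV (vial),medication,0.53
norepinephrine,Norepinephrine 10 mg (1 vial),medication,0.95
dobutamine,Dobutamine 250 mg (1 vial),medication,1.38
levosimendan,Levosimendan (vial-course),medication,581.63
oral_paste,Oral paste/day,medication,5.50
decontam_solution,Decontaminating solution,medication,10.00
effluent_bag,Effluent bag,medication,8.98
ccu_day,Coronary care unit (day),stay,909.79
icu_day,ICU (day),stay,1266.95
ward_day,Hospital ward (day),stay,234.12
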