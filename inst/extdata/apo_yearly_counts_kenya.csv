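outcome,year,count
low_birth_weight,2016,38440
low_birth_weight,2017,23162
low_birth_weight,2018,43150
low_birth_weight,2019,46051
stillbirth,2016,16888
stillbirth,2017,11381
stillbirth,2018,17781
stillbirth,2019,17810
preterm_birth,2016,23597
preterm_birth,2017,15672
preterm_birth,2018,24976
preterm_birth,2019,27437
neonatal_death,2016,9891
neonatal_death,2017,5688
neonatal_death,2018,9959
neonatal_death,2019,10157
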