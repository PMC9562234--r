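CamParChr1A	31000000	31100000	region01
CamParChr1A	33300000	33400000	region02
CamParChr1A	41000000	41100000	region03
CamParChr2	13900000	14000000	region04
CamParChr2	14950000	15100000	region05
CamParChr2	22450000	22550000	region06
CamParChr2	126750000	126850000	region07
CamParChr2	127050000	127150000	region08
CamParChr3	39700000	39800000	region09
CamParChr3	60450000	60550000	region10
CamParChr3	107750000	107850000	region11
CamParChr1	5000000	5120000	region12
CamParChr1	12500000	12600000	region13
CamParChr1	23000000	23150000	region14
CamParChr1	31000000	31080000	region15
CamParChr1	44000000	44100000	region16
CamParChr1	52000000	52200000	region17
CamParChr1	61000000	61090000	region18
CamParChr1	70000000	70100000	region19
CamParChr1A	2000000	2100000	region20
CamParChr1A	9000000	9150000	region21
CamParChr1A	18000000	18100000	region22
CamParChr2	40000000	40120000	region23
CamParChr2	55000000	55100000	region24
CamParChr2	68000000	68200000	region25
CamParChr3	5000000	5100000	region26
CamParChr3	18000000	18080000	region27
CamParChr3	88000000	88100000	region28
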