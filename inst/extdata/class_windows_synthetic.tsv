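class	rt_min	rt_max	mz_min	mz_max
TG	0.8	1.6	700	1050
DG	1.8	2.4	500	750
CE	2.6	3.1	550	800
PE	3.4	4.1	600	850
PC	4.4	5.2	650	900
SM	5.5	6.2	620	880
LPC	6.5	7.2	420	650
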