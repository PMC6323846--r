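sample_id	KD_nM	ka	kd
xynF1_upstream_1	311	7.14e4	2.22e-2
XRE-WT	656	5.99e4	3.93e-2
egl-242	40.6	1.24e5	5.04e-3
egl-363	68.7	1.23e5	8.44e-3
egl-617	48.4	9.06e4	4.39e-3
abf-687	133	9.85e4	1.31e-2
abf-830	144	1.54e5	2.22e-2
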