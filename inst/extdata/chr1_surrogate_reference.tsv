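# Published surrogate-test summary for the 38 dense SNP subsequences of the
# chromosome 1 haplotype of the NA12878 reference individual: correlation
# dimension of the original coordinate series, min/max over 10 phase-
# randomized surrogates, and the largest Lyapunov exponent (Eckmann).
id	d2_original	d2_surr_min	d2_surr_max	lle
S1	0.36627	0.39204	0.58594	0.33360
S2	0.13629	0.04635	0.05898	0.13629
S3	0.43052	0.71659	0.51951	0.34368
S4	0.26051	0.27251	0.54544	-0.05953
S5	0.35052	0.40979	0.57804	0.64071
S6	0.10796	0.10934	0.16225	0.26067
S7	0.25108	0.29168	0.38618	0.69047
S8	0.23778	0.25782	0.47653	0.24444
S9	0.35097	0.35113	0.62711	0.03415
S10	0.27321	0.26391	0.55738	0.47606
S11	0.31865	0.36589	1.00820	-0.05989
S12	0.10715	0.12004	0.15777	0.83138
S13	0.39225	0.45739	0.67238	0.30744
S14	0.47752	0.58567	0.75620	0.29638
S15	0.43977	0.49288	0.81505	0.03177
S16	0.18912	0.19767	0.30535	-0.03274
S17	0.53972	0.60917	0.95226	-0.10400
S18	0.27841	0.28615	0.42475	0.35364
S19	0.45505	0.50642	0.65790	0.33360
S20	0.47605	0.55843	0.90008	-0.10132
S21	0.18262	0.20794	0.39612	0.01682
S22	0.11989	0.13120	0.19777	0.83163
S23	0.10483	0.10412	0.13882	0.37704
S24	0.54638	0.29920	0.54770	1.13682
S25	0.07839	0.08140	0.12628	0.97159
S26	0.09959	0.09959	0.13728	0.60269
S27	0.13594	0.13708	0.25053	0.86333
S28	0.15408	0.16693	0.25944	0.76313
S29	0.43850	0.51500	0.83745	0.13629
S30	0.13553	0.13878	0.30403	0.18735
S31	0.09739	0.09993	0.18582	-0.03322
S32	0.14369	0.15750	0.22236	0.53379
S33	0.24935	0.28596	0.64447	0.43406
S34	0.16918	0.18759	0.25632	0.60329
S35	0.44667	0.47550	0.71674	0.35169
S36	0.30748	0.31783	0.72264	0.13042
S37	0.07777	0.07777	0.10733	-0.02983
S38	0.31624	0.39668	0.93261	0.34368
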