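Classification	Prevalence	rSpouse	rFS	rFD	rMS	rMD	rMZM	rMZF	rDZM	rDZF	rDOS	rBB	rSS	rBS
blond	0.394	0.226	0.364	0.361	0.454	0.472	0.959	0.972	0.357	0.337	0.454	0.417	0.375	0.442
brown	0.527	0.144	0.190	0.238	0.351	0.413	0.935	0.967	0.375	0.373	0.416	0.375	0.383	0.421
red	0.045	0.528	0.576	0.485	0.725	0.593	0.978	0.934	0.477	0.610	0.608	0.406	0.529	0.636
black	0.034	-0.179	0.334	0.352	0.413	0.274	0.928	0.991	0.706	0.857	0.567	0.143	0.752	0.570
light_vs_dark	0.439	0.229	0.387	0.380	0.472	0.476	0.957	0.971	0.375	0.398	0.478	0.481	0.407	0.490
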