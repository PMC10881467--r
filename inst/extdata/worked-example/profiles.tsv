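ucne	chrom	start	end	open	high_confidence	dnase_stages	scatac	marks	state
U1	chrZ	10000	10350	TRUE	FALSE	ED74-85			open_only
U2	chrZ	30000	30400	TRUE	FALSE		GanglionPrecursors::ED59	H3K27ac::FW13/14,H3K27ac::adult,H3K4me1::FW13/14	sustained_adult
U3	chrZ	50000	50300	FALSE	FALSE				none
U4	chrZ	70000	70250	TRUE	TRUE	ED74-85	Rods::ED113	H3K4me1::FW15/16	marked
U5	chrZ	95000	95400	TRUE	FALSE		Cones::ED113		open_only
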