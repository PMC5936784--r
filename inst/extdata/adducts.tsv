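# Singly charged positive counter-ions. mass_shift is electron-corrected:
# mass of the neutral adduct group minus one electron mass (0.00054858 Da),
# because observed m/z is the mass of the +1 cation.
name	group_formula	mass_shift	charge
+H+	H	1.00727645	1
+NH4+	NH4	18.03382555	1
+Na+	Na	22.98922070	1
+K+	K	38.96315810	1
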