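quantity	value
samples_2019	775
samples_2020	1040
samples_total	1815
raw_otus	52981
insect_otus	50087
insect_species	11776
validated_expert	11030
validated_gbif	9254
validated_gbol	10574
validated_species	10803
plausible_species_family	21043
plausible_species_order	22496
known_insect_species_germany	35500
barcoded_insect_species_germany	13076
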