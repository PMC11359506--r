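# Tissue compartments and their conductivities (S/m) at the 100 kHz
# excitation frequency, plus the boneless-reference configurations.

TISSUES <- c("skin", "fat_subcut", "fat_intra", "muscle", "bone", "marrow")

TISSUE_SIGMA <- c(skin = 0.065, fat_subcut = 0.03, fat_intra = 0.03,
                  muscle = 0.37, bone = 0.02, marrow = 0.002)

TISSUE_CODES <- stats::setNames(seq_along(TISSUES), TISSUES)

CONFIGS <- c("cfg1_homogeneous", "cfg2_skin_fat", "cfg3_skin_fat_intra")
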