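"list","gene"
"mitochondrial","MT-ND1"
"mitochondrial","MT-ND2"
"mitochondrial","MT-CO1"
"mitochondrial","MT-CO2"
"mitochondrial","MT-ATP8"
"mitochondrial","MT-ATP6"
"mitochondrial","MT-CO3"
"mitochondrial","MT-ND3"
"mitochondrial","MT-ND4L"
"mitochondrial","MT-ND4"
"mitochondrial","MT-ND5"
"mitochondrial","MT-ND6"
"mitochondrial","MT-CYB"
"hemoglobin","HBB"
"hemoglobin","HBA1"
"hemoglobin","HBA2"
"stress_markers","FOS"
"stress_markers","FOSB"
"stress_markers","JUN"
"stress_markers","JUNB"
"stress_markers","JUND"
"stress_markers","EGR1"
"stress_markers","ATF3"
"stress_markers","HSPA1A"
"stress_markers","HSPA1B"
"stress_markers","HSPA8"
"stress_markers","DNAJB1"
"stress_markers","ZFP36"
"stress_markers","IER2"
"stress_markers","IER3"
"stress_markers","NR4A1"
"stress_markers","DUSP1"
"stress_markers","SOCS3"
"stress_markers","KLF6"
"stress_markers","BTG2"
"stress_markers","CYR61"
"ribosomal","RPS1"
"ribosomal","RPS2"
"ribosomal","RPS3"
"ribosomal","RPS4"
"ribosomal","RPS5"
"ribosomal","RPS6"
"ribosomal","RPS7"
"ribosomal","RPS8"
"ribosomal","RPS9"
"ribosomal","RPS10"
"ribosomal","RPS11"
"ribosomal","RPS12"
"ribosomal","RPS13"
"ribosomal","RPS14"
"ribosomal","RPS15"
"ribosomal","RPL1"
"ribosomal","RPL2"
"ribosomal","RPL3"
"ribosomal","RPL4"
"ribosomal","RPL5"
"ribosomal","RPL6"
"ribosomal","RPL7"
"ribosomal","RPL8"
"ribosomal","RPL9"
"ribosomal","RPL10"
"ribosomal","RPL11"
"ribosomal","RPL12"
"ribosomal","RPL13"
"ribosomal","RPL14"
"ribosomal","RPL15"
"proliferation_markers","MKI67"
"proliferation_markers","CCNB1"
"proliferation_markers","CCNB2"
"proliferation_markers","CDK1"
"proliferation_markers","TOP2A"
"proliferation_markers","BUB1"
"proliferation_markers","PLK1"
"proliferation_markers","AURKA"
"proliferation_markers","UBE2C"
"proliferation_markers","CENPF"
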