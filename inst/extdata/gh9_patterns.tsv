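# GH9 cellulase pattern set (PROSITE syntax), one per line: id<TAB>pattern
# region1: conserved Region I (PROSITE PS60032); contains the DAGD motif.
# region2: conserved Region II (revised PROSITE PS00592).
# region3: stand-in anchored on the invariant catalytic acid E and the
#          downstream nucleophilic D (no community pattern exists for Region III).
# insertion: algal-specific four-residue insertion found in Region II.
# hevein: CBM18 Hevein cysteine-spacing motif (subscript dialect).
region1	[LVS]-x-[GK]-G-[WFYLM]-[YHF]-D-[ACGS]-G-[DSN]-X(2)-[KMR]-[FAILY]-X-[FWYLQTV]-[APTNS]-[MLGAQS]
region2	[HLY]-[AILMV]-[FIL]-G-x-[NSTW]-x(2,4)-[SCTV]-[FY]-[LIVMFY]-[SITV]-G-x(1,5)-[GSY]-x(2)-[AFPSTY]-[FLPSV]-x(2)-[AILPQVM]-[HV]-[DHLS]-[KRS]
region3	E-x(0,12)-D
insertion	P-T-[PTA]-[YSG]
hevein	[CG]X_5-7_[C]X_4_[CCS]X_4_[C]X_6_[C]X_3_[C][CG]X_8_[C]X_5_[CCS]X_4_[C]X_7_[C]
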