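# Kyamicin core structure. The 19-residue core sequence is transcribed from
# the published mature-structure figure; the transcription is validated by
# the derived mature elemental formula, which must equal the published
# C76H108N20O25S3. Positions are 1-based. Three methyllanthionine bridges
# (Thr4/Thr11/Thr18 each paired with a Cys), a lysinoalanine bridge between
# the dehydrated Ser6 and Lys19, and a beta-hydroxylated Asp15.
name: kyamicin
core_sequence: CGSTCSFGPFTGVCDGSTK
dehydrations: [4, 6, 11, 18]
thioether_bridges:
- [1, 18]
- [4, 14]
- [5, 11]
lysinoalanine: [6, 19]
hydroxylations: [15]
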