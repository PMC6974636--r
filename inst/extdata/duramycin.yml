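# Duramycin core structure (cinnamycin with Lys2). Ser4 forms a lanthionine
# with Cys14; Thr11 and Thr18 form methyllanthionines with Cys5 and Cys1;
# lysinoalanine between Ser6 and Lys19; beta-hydroxy-Asp15. Mature formula
# C89H125N23O25S3.
name: duramycin
core_sequence: CKQSCSFGPFTFVCDGNTK
dehydrations: [4, 6, 11, 18]
thioether_bridges:
- [1, 18]
- [4, 14]
- [5, 11]
lysinoalanine: [6, 19]
hydroxylations: [15]
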