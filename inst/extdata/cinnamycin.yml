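# Cinnamycin core structure (Arg2 variant of the duramycin scaffold).
# Mature formula C89H125N25O25S3.
name: cinnamycin
core_sequence: CRQSCSFGPFTFVCDGNTK
dehydrations: [4, 6, 11, 18]
thioether_bridges:
- [1, 18]
- [4, 14]
- [5, 11]
lysinoalanine: [6, 19]
hydroxylations: [15]
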