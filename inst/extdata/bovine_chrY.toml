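# Default bovine chromosome-Y sexing assay: four-gene RNA-seq marker panel
# plus the multiplex PCR primer set (male-specific MSY pair and autosomal
# CDK1 control pair on chromosome 28).

[panel]
genes = ["ENSBIXG00000029763", "ENSBIXG00000029774", "ENSBIXG00000029788", "ENSBIXG00000029892"]
tau_female = 1.0
tau_male = 10.0

[[primer_pairs]]
name = "MSY"
forward = "AGGGTGAAGCAAATGGTCGT"
reverse = "GGAGCAACAGTGTCCTGTGT"
role = "male_specific"
expected_length = 279

[[primer_pairs]]
name = "CDK1"
forward = "GCCCAGACCCAGCATCATT"
reverse = "GGGAGTGCCCAAAGCTCTAAA"
role = "control"
expected_length = 590
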