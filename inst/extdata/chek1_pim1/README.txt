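Worked example: the CHEK1/PIM1 feed-forward-loop ceRNA network.

sponges.tsv + mir_targets.tsv carry the published network topology (15
circRNA-miRNA sponge edges over 7 circRNAs and 4 miRNAs, with AGO-CLIP
region p-value bounds) and the validated miRNA -> host-transcript records.
circ_annotation_synthetic.tsv coordinates, spliced lengths, and the
n_sites column of sponges.tsv are SYNTHETIC placeholders: the published
table reports neither coordinates nor per-edge site counts.
signature_host_genes.txt lists the 11 signature host genes of the circRNA
funnel stage.
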