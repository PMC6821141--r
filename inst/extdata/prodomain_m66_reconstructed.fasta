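>prodomain_M66_reconstructed residues 23-113 of human BDNF precursor with the Val66Met substitution, reconstructed offline (not a database download)
EANIRGQGGLAYPGVRTHGTLESVNGPKAGSRGLTSLADTFEHMIEELLDEDQKVRPNEE
NNKDADLYTSRVMLSSQVPLEPPLLFLLEYK
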