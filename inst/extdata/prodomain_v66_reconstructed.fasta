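>prodomain_V66_reconstructed residues 23-113 of human BDNF precursor, reconstructed offline from published blob sequences and residue anchors (not a database download)
EANIRGQGGLAYPGVRTHGTLESVNGPKAGSRGLTSLADTFEHVIEELLDEDQKVRPNEE
NNKDADLYTSRVMLSSQVPLEPPLLFLLEYK
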