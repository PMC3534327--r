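family	n_genes
DUF23	65
nsp-genes	58
DUF19	51
nlp-genes	44
DUF130	41
DUF13	35
DUF148	32
flp-genes	30
CW	28
DUF274	22
small DB proteins	18
DUF229	15
DUF1647	14
DUF263	13
DUF236	13
TF352284	13
DUF316	12
DUF273	12
DUF271	11
DUF268	11
DUF870	11
DUF672	10
DUF1261	10
TF319413	10
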