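protease_gene	substrate_uniprot	position	evidence
CTSD	P69905	109	synthetic-demo
CTSD	P69905	129	synthetic-demo
CTSD	P69905	131	synthetic-demo
MMP12	P02458	237	synthetic-demo
MMP8	P02458	237	synthetic-demo
MMP1	P02458	263	synthetic-demo
MMP13	P02458	237	synthetic-demo
MMP13	P39060	300	synthetic-demo
MMP13	P08123	528	synthetic-demo
MMP13	P08123	699	synthetic-demo
MMP14	P39060	300	synthetic-demo
MMP14	P08123	488	synthetic-demo
MMP14	P08123	739	synthetic-demo
CTSB	P39060	324	synthetic-demo
CTSK	P39060	324	synthetic-demo
CTSL	P39060	324	synthetic-demo
MMP20	P39060	324	synthetic-demo
MMP7	P39060	324	synthetic-demo
MMP2	P02452	599	synthetic-demo
MMP2	P08123	488	synthetic-demo
MMP2	P08123	739	synthetic-demo
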