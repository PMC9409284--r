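domain	segment	first	last	anchor
1	k	243	254	243
1	o	255	290	255
1	i	392	430	392
1	i	431	440	391
2	k	908	919	908
2	o	920	947	920
2	p	948	985	936
2	p	986	998	935
2	i	999	1040	999
3	k	1401	1412	1401
3	p	1448	1510	1448
3	i	1522	1560	1522
4	i	1821	1830	1821
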