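sample	likely_het	likely_mosaic
1802	205	16
1803	276	14
1804	293	9
1805	197	8
B071	277	11
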