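# GMC / AAO conserved-feature signatures (id<TAB>pattern)
ADP_BINDING	G-x-G-x(2)-G-x(18)-E
PS00623	[GA]-[RKNC]-x-[LIVW]-G(2)-[GST](2)-x-[LIVM]-[NH]-x(3)-[FYWA]-x(2)-[PAG]-x(5)-[DNESHQA]
PS00624	[GS]-[PSTA]-x(2)-[ST]-[PS]-x-[LIVM](2)-x(2)-S-G-[LIVM]-G
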