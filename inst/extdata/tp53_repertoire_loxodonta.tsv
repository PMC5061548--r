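gene	scaffold	is_retrogene	coding	orf_length
TP53	47	FALSE	TRUE	392
TP53RTG1	175	TRUE	FALSE	NA
TP53RTG2	217	TRUE	TRUE	134
TP53RTG3	406	TRUE	TRUE	79
TP53RTG4	627	TRUE	TRUE	134
TP53RTG5	221	TRUE	TRUE	162
TP53RTG6	76	TRUE	TRUE	123
TP53RTG7	208	TRUE	FALSE	NA
TP53RTG8	294	TRUE	TRUE	210
TP53RTG9	786	TRUE	FALSE	NA
TP53RTG10	221	TRUE	TRUE	210
TP53RTG11	281	TRUE	TRUE	203
TP53RTG12	825	TRUE	TRUE	180
TP53RTG13	458	TRUE	FALSE	NA
TP53RTG14	928	TRUE	TRUE	210
TP53RTG15	656	TRUE	TRUE	210
TP53RTG16	378	TRUE	FALSE	NA
TP53RTG17	552	TRUE	TRUE	111
TP53RTG18	498	TRUE	TRUE	111
TP53RTG19	342	TRUE	TRUE	210
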