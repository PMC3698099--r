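attribute_code	conformation	protein_id
DNMT	heterochromatic	SYN_DNMT_01
DNMT	heterochromatic	SYN_DNMT_02
DNMT	heterochromatic	SYN_DNMT_03
HAT	euchromatic	SYN_HAT_01
HAT	euchromatic	SYN_HAT_02
HAT	euchromatic	SYN_HAT_03
HAT	euchromatic	SYN_HAT_04
HDAC	heterochromatic	SYN_HDAC_01
HDAC	heterochromatic	SYN_HDAC_02
HDAC	heterochromatic	SYN_HDAC_03
HDAC	heterochromatic	SYN_HDAC_04
H3K4	euchromatic	SYN_H3K4_01
H3K4	euchromatic	SYN_H3K4_02
H3K4	euchromatic	SYN_H3K4_03
H3K36	euchromatic	SYN_H3K36_01
H3K36	euchromatic	SYN_H3K36_02
H3K79	euchromatic	SYN_H3K79_01
H3K79	euchromatic	SYN_H3K79_02
H3R17	euchromatic	SYN_H3R17_01
H3R17	euchromatic	SYN_H3R17_02
H3K9	heterochromatic	SYN_H3K9_01
H3K9	heterochromatic	SYN_H3K9_02
H3K9	heterochromatic	SYN_H3K9_03
H3K27	heterochromatic	SYN_H3K27_01
H3K27	heterochromatic	SYN_H3K27_02
H3K27	heterochromatic	SYN_H3K27_03
H4K20	heterochromatic	SYN_H4K20_01
H4K20	heterochromatic	SYN_H4K20_02
H3K4i	heterochromatic	SYN_H3K4i_01
H3K4i	heterochromatic	SYN_H3K4i_02
H3K4i	heterochromatic	SYN_H3K4i_03
H3K36i	heterochromatic	SYN_H3K36i_01
H3K36i	heterochromatic	SYN_H3K36i_02
H3R2i	heterochromatic	SYN_H3R2i_01
H3R2i	heterochromatic	SYN_H3R2i_02
H4R3i	heterochromatic	SYN_H4R3i_01
H4R3i	heterochromatic	SYN_H4R3i_02
H3K27i	euchromatic	SYN_H3K27i_01
H3K27i	euchromatic	SYN_H3K27i_02
H3S10	euchromatic	SYN_H3S10_01
H3S10	euchromatic	SYN_H3S10_02
H3S10	euchromatic	SYN_H3S10_03
H3S10i	heterochromatic	SYN_H3S10i_01
H3S10i	heterochromatic	SYN_H3S10i_02
ATP	ambivalent	SYN_ATP_01
ATP	ambivalent	SYN_ATP_02
ATP	ambivalent	SYN_ATP_03
ATP	ambivalent	SYN_ATP_04
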