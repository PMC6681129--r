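peak_id	structure_labels	dominant_index
GP1	A2	1
GP2	FA2	1
GP3	A2(6)BG1	1
GP4	FA2B	1
GP5	M5	1
GP6	FA2G1	1
GP7	FA2BG1	1
GP8	A2G2	1
GP9	M6	1
GP10	FA2G2	1
GP11	FA2BG2	1
GP12	A2G1S(3)1	1
GP13	FA2G1S(3)1 + M7	1
GP14	A2G2S(6)1 + A2G2S(3)1	1
GP15	FA2G2S(6)1 + FA2G2S(3)1	1
GP16	FA2BG2S(3)1 + FA2BG2S(6)1	1
GP17	A2BG2S(3)1 + M8	1
GP18	M9	1
GP19	A2G2S(3,6)2 + A2G2S(6,6)2 + A2G2S(3,3)2	1
GP20	FA2G2S(3,6)2 + FA2G2S(6,6)2 + FA2G2S(3,3)2	1
GP21	FA2BG2S(3,6)2 + FA2BG2S(6,6)2 + FA2BG2S(3,3)2	1
GP22	A3G3S(3,6)2	1
GP23	A3G3S(3,3)2	1
GP24	A3G3S(3,3,3)3	1
GP25	A3G3S(3,3,6)3	1
GP26	FA3G3S(3,3,3)3	1
GP27	A3F1G3S(3,3)2	1
GP28	A3BG3S(3,3,3)3	1
GP29	A3F1G3S(3,3,3)3 + A3F1G3S(3,3,6)3	1
GP30	A4G4S(3,3,3)3	1
GP31	A4G4S(3,3,6)3	1
GP32	A4F1G3S(3,3,3)3 + A4F1G3S(3,3,6)3 + A4F1G3S(3,6,6)3	1
GP33	A4G4S(3,3,3,3)4	1
GP34	A4G4S(3,3,3,6)4	1
GP35	A4F1G4S(3,3,3,3)4	1
GP36	A4F1G4S(3,3,3,6)4	1
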