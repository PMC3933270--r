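specimen	ontogenetic_rank	frill_length_mm
TMP1982.016.0011	1	225
TMP1980.054.0001	2	575
TMP1992.082.0001	3	587
ROM767	4	580
CMN8798	5	590
TMP1994.182.0001	6	645
CMN971	7	620
AMNHFARB5351	8	679
UALVP11735	9.5	656
TMP1997.085.0001	9.5	695
CMN8795	11	688
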