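# Example tripeptide activity table. The four catch-all-class (XXX)
# peptides LVQ, LVE, IWH and GPM are the published ones; the remaining
# rows are synthetic fillers with invented IC50 values, for tests and
# demonstrations only.
sequence	ic50_uM	source
IPP	5	synthetic filler
VPP	9	synthetic filler
HLP	12	synthetic filler
MEG	15	synthetic filler
WIL	7	synthetic filler
QGV	18	synthetic filler
LVQ	5	published catch-all class
LVE	12	published catch-all class
IWH	3.5	published catch-all class
GPM	17	published catch-all class
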