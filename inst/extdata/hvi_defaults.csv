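key,hvi_pct_per_C,basis,source_note
South America,2.34,non_accidental,continental average
Africa,2.34,non_accidental,lowest continental average (South America) applied for lack of African data
Southeast Asia,5.29,non_accidental,continental average
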