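occurrence_id,taxon_or_clade,age_min,age_max
o1,tA,280,285
o2,tB,282,286
o3,tA+tB,291,295
o4,tC,276,276
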