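stratum_id,region,bcr,area_km2
S01,region-01,BCR-01,33974
S02,region-02,BCR-02,31216
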