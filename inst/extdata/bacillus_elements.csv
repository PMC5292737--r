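element_id,taxon,degenerate,fragment,indel_profile
R2Ba,atticus,FALSE,FALSE,
R2BggA,grandii_grandii,FALSE,FALSE,
R2BggB,grandii_grandii,FALSE,FALSE,
R2Bgb,benazzii,FALSE,FALSE,
R2Bgm,maretimi,FALSE,FALSE,
R2Bgmdel,maretimi,FALSE,FALSE,del:1035-1460
R2Brfun,rossius,FALSE,FALSE,
R2Brdeg,rossius,TRUE,FALSE,
R2Brdel,rossius,FALSE,TRUE,del:1035-1460
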