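mesh: .......................................1..........

══ Failed ══════════════════════════════════════════════════════════════════════
── 1. Failure ('test-mesh.R:69:3'): icosphere facet areas become more uniform wi
all(diff(cv) < 0) is not TRUE

`actual`:   FALSE
`expected`: TRUE 

══ DONE ════════════════════════════════════════════════════════════════════════
## mesh done in 0.807627 secs
headmodel: ..............................

══ DONE ════════════════════════════════════════════════════════════════════════
## headmodel done in 0.4369617 secs
sphere-oracle: ............

══ DONE ════════════════════════════════════════════════════════════════════════
## sphere-oracle done in 0.6586123 secs
electrodes: ................

══ DONE ════════════════════════════════════════════════════════════════════════
## electrodes done in 2.139713 secs
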