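>mmu-miR-203-3p
GUGAAAUGUUUAGGACCACUAG
>mmu-miR-205-5p
UCCUUCAUUCCACCGGAGUCUG
>mmu-miR-21a-5p
UAGCUUAUCAGACUGAUGUUGA
>mmu-let-7a-5p
UGAGGUAGUAGGUUGUAUAGUU
>mmu-miR-16-5p
UAGCAGCACGUAAAUAUUGGCG
>mmu-miR-199a-3p
ACAGUAGUCUGCACAUUGGUUA
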