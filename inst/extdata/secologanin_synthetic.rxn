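# Secologanin synthase: Loganin + NADPH + H+ + O2 <=> Secologanin + NADP+ + H2O
# Compound structures in secologanin_synthetic.sdf are small synthetic
# placeholders; the reaction topology (participants, sides, pair types)
# is the real one. H+/H2O carry the 'leave' pair type; O2 participates
# through group edges only.
reaction: RSECO
ec: 1.3.3.9
substrates: LOGANIN NADPH HPLUS O2
products: SECOLOGANIN NADP H2O
pair: LOGANIN SECOLOGANIN main
pair: NADPH NADP cofactor
pair: HPLUS H2O leave
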